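#' Extract the four splice-site sequences of an event
#'
#' Donor (5'-ss) sites are 9-mers: the last 3 exonic bases plus the first 6
#' intronic bases; acceptor (3'-ss) sites are 23-mers: the last 20 intronic
#' bases plus the first 3 exonic bases. On `"-"` strand events the mirrored
#' genomic slices are reverse-complemented so the canonical GT / AG
#' dinucleotides appear in reading orientation (donor positions 4-5,
#' acceptor positions 19-20). `"unknown"`-strand events are extracted as
#' `"+"`.
#'
#' @param ev One event row.
#' @param genome Genome (FASTA path, `DNAStringSet`, or named character).
#' @return Named character vector with elements `upI_ss5`, `upI_ss3`,
#'   `dnI_ss5`, `dnI_ss3`.
#' @export
extract_site_sequences <- function(ev, genome) {
  genome <- as_genome(genome)
  sl <- function(s, e) genome_slice(genome, ev$chrom, s, e)
  if (ev$strand == "-") {
    # donor boundary p: intron runs genomically leftward from p
    donor <- function(p) revcomp(sl(p - 6L, p + 3L))
    accep <- function(p) revcomp(sl(p - 3L, p + 20L))
  } else {
    donor <- function(p) sl(p - 3L, p + 6L)
    accep <- function(p) sl(p - 20L, p + 3L)
  }
  c(upI_ss5 = donor(ev$upI_ss5), upI_ss3 = accep(ev$upI_ss3),
    dnI_ss5 = donor(ev$dnI_ss5), dnI_ss3 = accep(ev$dnI_ss3))
}

# ---- maximum-entropy site model --------------------------------------

.seq_matrix <- function(seqs, len, alphabet) {
  m <- do.call(rbind, strsplit(seqs, ""))
  if (ncol(m) != len) stop("sequences must all have length ", len)
  bad <- !apply(m, 1, function(r) all(r %in% alphabet))
  if (any(bad)) {
    warning(sum(bad), " sequence(s) with symbols outside the alphabet ",
            "rejected")
    m <- m[!bad, , drop = FALSE]
  }
  if (!nrow(m)) stop("training error: no usable sequences")
  m
}

# position marginals (len x K) and adjacent-pair marginals (list of K x K)
.empirical_marginals <- function(m, alphabet) {
  len <- ncol(m); K <- length(alphabet)
  node <- matrix(0, len, K, dimnames = list(NULL, alphabet))
  for (i in seq_len(len)) {
    t <- table(factor(m[, i], levels = alphabet))
    node[i, ] <- as.numeric(t) / nrow(m)
  }
  pair <- vector("list", max(len - 1L, 0L))
  for (i in seq_len(len - 1L)) {
    t <- table(factor(m[, i], levels = alphabet),
               factor(m[, i + 1L], levels = alphabet))
    pair[[i]] <- unclass(t / nrow(m))
  }
  list(node = node, pair = pair)
}

# forward-backward on the chain defined by node potentials `w` (len x K)
# and edge potentials `W` (list of K x K); returns Z, node and pair
# marginals. Potentials are plain nonnegative reals; messages are
# normalized per position to avoid under/overflow.
.chain_marginals <- function(w, W) {
  len <- nrow(w); K <- ncol(w)
  alpha <- matrix(0, len, K); beta <- matrix(0, len, K)
  scale <- numeric(len)
  a <- w[1, ]
  scale[1] <- sum(a); alpha[1, ] <- a / scale[1]
  for (i in seq_len(len - 1L)) {
    a <- as.numeric(alpha[i, ] %*% W[[i]]) * w[i + 1L, ]
    scale[i + 1L] <- sum(a)
    alpha[i + 1L, ] <- a / scale[i + 1L]
  }
  beta[len, ] <- 1
  for (i in rev(seq_len(len - 1L))) {
    b <- as.numeric(W[[i]] %*% (w[i + 1L, ] * beta[i + 1L, ]))
    beta[i, ] <- b / sum(b)   # scale cancels in normalized marginals
  }
  node <- alpha * beta
  node <- node / rowSums(node)
  pair <- vector("list", max(len - 1L, 0L))
  for (i in seq_len(len - 1L)) {
    pm <- outer(alpha[i, ], w[i + 1L, ] * beta[i + 1L, ]) * W[[i]]
    pair[[i]] <- pm / sum(pm)
  }
  list(logZ = sum(log(scale)), node = node, pair = pair)
}

#' Train a maximum-entropy splice-site model
#'
#' Fits the maximum-entropy distribution over fixed-length sequences whose
#' constrained marginals match the training set: order 1 constrains each
#' position's nucleotide frequencies, order 2 additionally constrains all
#' adjacent-position pair frequencies. With adjacent-pair constraints the
#' solution is a chain-structured exponential family, so it is fitted by
#' iterative proportional scaling with exact marginals from
#' forward-backward message passing - the full sequence space (4^23 for
#' acceptors) is never enumerated. With order-1 constraints only, the
#' solution factorizes into the product of positional marginals (a PWM).
#' The background model is the position-independent nucleotide composition
#' of the decoy set (uniform if no decoys are given).
#'
#' @param signal_seqs Character vector of aligned site sequences (>= 50 for
#'   real use; shorter sets train but warn).
#' @param decoy_seqs Character vector of background sequences, or `NULL`.
#' @param kind `"donor5"` (length 9), `"acceptor3"` (length 23) or
#'   `"custom"` (any fixed length).
#' @param constraint_order Subset of `c(1, 2)`; default both.
#' @param alphabet Residue alphabet; default `A,C,G,T`.
#' @param tol Maximum absolute error on any constrained marginal at
#'   convergence. Default 1e-4.
#' @param max_iter Maximum scaling sweeps.
#' @return Object of class `maxent_model`.
#' @export
train_maxent <- function(signal_seqs, decoy_seqs = NULL,
                         kind = c("donor5", "acceptor3", "custom"),
                         constraint_order = c(1, 2),
                         alphabet = c("A", "C", "G", "T"),
                         tol = 1e-4, max_iter = 2000L) {
  kind <- match.arg(kind)
  if (!length(signal_seqs)) stop("training error: empty signal set")
  len <- switch(kind, donor5 = 9L, acceptor3 = 23L,
                custom = nchar(signal_seqs[1]))
  stopifnot(all(constraint_order %in% c(1, 2)), length(constraint_order) >= 1)
  if (length(signal_seqs) < 50)
    warning("fewer than 50 signal sequences; marginals will be noisy")
  m <- .seq_matrix(signal_seqs, len, alphabet)
  emp <- .empirical_marginals(m, alphabet)
  K <- length(alphabet)

  if (is.null(decoy_seqs)) {
    bg <- stats::setNames(rep(1 / K, K), alphabet)
  } else {
    dm <- .seq_matrix(decoy_seqs, len, alphabet)
    t <- table(factor(as.vector(dm), levels = alphabet))
    bg <- as.numeric(t) / sum(t)
    names(bg) <- alphabet
  }

  use_pairs <- (2 %in% constraint_order) && len >= 2L
  if (!use_pairs) {
    # order-1 maxent factorizes: PWM of positional marginals
    w <- emp$node
    W <- lapply(seq_len(max(len - 1L, 0L)),
                function(i) matrix(1, K, K, dimnames = list(alphabet, alphabet)))
    fit <- .chain_marginals(w, W)
    err <- 0; iters <- 0L
  } else {
    w <- matrix(1, len, K, dimnames = list(NULL, alphabet))
    W <- lapply(emp$pair, function(p) {
      M <- matrix(1, K, K, dimnames = list(alphabet, alphabet)); M
    })
    iters <- 0L; err <- Inf
    while (iters < max_iter) {
      iters <- iters + 1L
      # sequential scaling: each factor is rescaled against marginals
      # recomputed after the previous update (parallel updates oscillate)
      for (i in seq_len(len - 1L)) {
        fit <- .chain_marginals(w, W)
        ratio <- ifelse(fit$pair[[i]] > 0, emp$pair[[i]] / fit$pair[[i]], 0)
        W[[i]] <- W[[i]] * ratio
        W[[i]] <- W[[i]] / max(W[[i]])   # keep potentials bounded
      }
      fit <- .chain_marginals(w, W)
      err <- max(c(
        abs(fit$node - emp$node),
        unlist(Map(function(a, b) abs(a - b), fit$pair, emp$pair))))
      if (err <= tol) break
    }
    if (err > tol)
      warning("maxent fit stopped at marginal error ", signif(err, 3))
  }
  structure(list(kind = kind, length = len, alphabet = alphabet,
                 constraint_order = sort(unique(constraint_order)),
                 node_pot = w, edge_pot = W, logZ = fit$logZ,
                 fitted_node = fit$node, fitted_pair = fit$pair,
                 background = bg, n_signal = nrow(m),
                 marginal_error = err, iterations = iters),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat("maxent splice-site model (", x$kind, "): length ", x$length,
      ", constraints order {", paste(x$constraint_order, collapse = ","),
      "}, ", x$n_signal, " training sites, marginal error ",
      signif(x$marginal_error, 3), "\n", sep = "")
  invisible(x)
}

# log probability of sequences under the fitted signal distribution
.signal_logprob <- function(model, seqs) {
  m <- .seq_matrix(seqs, model$length, model$alphabet)
  idx <- matrix(match(m, model$alphabet), nrow = nrow(m))
  lp <- numeric(nrow(m))
  for (r in seq_len(nrow(m))) {
    v <- log(model$node_pot[cbind(seq_len(model$length), idx[r, ])])
    e <- if (model$length > 1)
      vapply(seq_len(model$length - 1L),
             function(i) log(model$edge_pot[[i]][idx[r, i], idx[r, i + 1L]]),
             numeric(1)) else 0
    lp[r] <- sum(v) + sum(e) - model$logZ
  }
  lp
}

#' Score site sequences with a maxent model
#'
#' The MaxEnt score is the log2-odds of a sequence under the fitted signal
#' distribution versus the background composition. Probabilities are
#' floored at 1e-12, so every ACGT sequence scores finitely.
#'
#' @param model A [train_maxent()] model.
#' @param seqs Character vector of sequences of the model's length.
#' @return Numeric vector of log2-odds scores.
#' @export
score_site <- function(model, seqs) {
  stopifnot(inherits(model, "maxent_model"))
  if (any(nchar(seqs) != model$length))
    stop("input error: sequence length does not match model (",
         model$length, ")")
  floor_p <- 1e-12
  p_sig <- pmax(exp(.signal_logprob(model, seqs)), floor_p)
  m <- .seq_matrix(seqs, model$length, model$alphabet)
  idx <- matrix(match(m, model$alphabet), nrow = nrow(m))
  p_bg <- pmax(exp(rowSums(matrix(log(model$background[idx]),
                                  nrow = nrow(m)))), floor_p)
  log2(p_sig / p_bg)
}

#' Per-event splice-site competition score
#'
#' \eqn{\Delta_{ss5}} = score(upI_ss5) - score(dnI_ss5) compares the two
#' donors competing for the downstream acceptor; \eqn{\Delta_{ss3}} =
#' score(dnI_ss3) - score(upI_ss3) compares the two acceptors competing for
#' the upstream donor; their sum S summarizes the net competition. Weaker
#' middle-exon-flanking sites (dnI_ss5, upI_ss3) give larger S, i.e. a
#' higher priority for pairing upI_ss5 with dnI_ss3 and producing the
#' skipping isoform.
#'
#' @param scores Numeric vector or data.frame with elements/columns
#'   `upI_ss5`, `upI_ss3`, `dnI_ss5`, `dnI_ss3`.
#' @return data.frame with `delta_ss5`, `delta_ss3`, `S` (plus the four
#'   input scores).
#' @export
competition_score <- function(scores) {
  s <- as.data.frame(as.list(scores))
  stopifnot(all(c("upI_ss5", "upI_ss3", "dnI_ss5", "dnI_ss3") %in% names(s)))
  s$delta_ss5 <- s$upI_ss5 - s$dnI_ss5
  s$delta_ss3 <- s$dnI_ss3 - s$upI_ss3
  s$S <- s$delta_ss5 + s$delta_ss3
  s
}

# ---- Mann-Whitney -----------------------------------------------------

#' Two-sided Mann-Whitney U test
#'
#' For small samples (both sizes <= `exact_max`) the null distribution of
#' the rank-sum statistic is computed exactly by dynamic programming over
#' the (tie-averaged, doubled) pooled ranks, so tied data are handled
#' exactly; the two-sided p-value is `min(1, 2 min(P(U <= u), P(U >= u)))`.
#' Larger samples use the normal approximation with tie-corrected variance
#' (no continuity correction).
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest per-group size for the exact path. Default 8.
#' @return List with `U` (for `x`), `p_value`, `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 8L) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("statistics error: empty group")
  pooled <- c(x, y)
  r <- rank(pooled)
  R1 <- sum(r[seq_len(n1)])
  U <- R1 - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    # exact distribution of the rank sum over all C(n1+n2, n1) labelings:
    # DP over items with weights 2*rank (integers even under ties .5)
    wts <- as.integer(round(2 * r))
    total <- sum(wts)
    # dp[k+1, s+1] = number of k-subsets with doubled-rank sum s
    dp <- matrix(0, nrow = n1 + 1L, ncol = total + 1L)
    dp[1, 1] <- 1
    for (wt in wts) {
      for (k in n1:1) {
        shifted <- c(rep(0, wt), dp[k, seq_len(total + 1L - wt)])
        dp[k + 1L, ] <- dp[k + 1L, ] + shifted
      }
    }
    counts <- dp[n1 + 1L, ]
    sums2 <- which(counts > 0) - 1L      # doubled rank sums
    obs2 <- as.integer(round(2 * R1))
    cnt <- counts[counts > 0]
    ntot <- sum(cnt)
    p_le <- sum(cnt[sums2 <= obs2]) / ntot
    p_ge <- sum(cnt[sums2 >= obs2]) / ntot
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    N <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    z <- (U - n1 * n2 / 2) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(U = U, p_value = p, method = method)
}

#' Compare splice-site strengths between SIDG and IIDG groups
#'
#' Summarizes per-site-class score distributions (mean and SD per group)
#' and tests each class - the four sites plus the competition score S -
#' with a two-sided Mann-Whitney test. Parenthesized dispersion values in
#' the summary are standard deviations.
#'
#' @param scores_sidg,scores_iidg data.frames with columns `upI_ss5`,
#'   `upI_ss3`, `dnI_ss5`, `dnI_ss3` (and optionally `S`; computed if
#'   absent).
#' @return data.frame: one row per site class with `mean_sidg`, `sd_sidg`,
#'   `mean_iidg`, `sd_iidg`, `p_value`.
#' @export
compare_site_strengths <- function(scores_sidg, scores_iidg) {
  if (!nrow(scores_sidg) || !nrow(scores_iidg))
    stop("statistics error: empty group")
  if (!"S" %in% names(scores_sidg)) scores_sidg <- competition_score(scores_sidg)
  if (!"S" %in% names(scores_iidg)) scores_iidg <- competition_score(scores_iidg)
  classes <- c("upI_ss5", "upI_ss3", "dnI_ss5", "dnI_ss3", "S")
  rows <- lapply(classes, function(cl) {
    a <- scores_sidg[[cl]]; b <- scores_iidg[[cl]]
    mw <- mann_whitney(a, b)
    data.frame(site = cl, mean_sidg = mean(a), sd_sidg = stats::sd(a),
               mean_iidg = mean(b), sd_iidg = stats::sd(b),
               p_value = mw$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---- model serialization ---------------------------------------------

#' Serialize / restore a maxent model as a text table
#'
#' Versioned plain-text format: a header section, the background
#' composition, node potentials and edge potentials, written with full
#' numeric precision.
#'
#' @param model A `maxent_model`.
#' @param path File path.
#' @return `read_maxent_model` returns the restored model.
#' @export
write_maxent_model <- function(model, path) {
  con <- file(path, "w"); on.exit(close(con))
  num <- function(x) sprintf("%.17g", x)
  writeLines(c("# gess maxent model v1",
               paste("kind", model$kind),
               paste("length", model$length),
               paste("alphabet", paste(model$alphabet, collapse = ",")),
               paste("constraint_order",
                     paste(model$constraint_order, collapse = ",")),
               paste("logZ", num(model$logZ)),
               paste("n_signal", model$n_signal),
               paste("background", paste(num(model$background),
                                         collapse = ","))), con)
  for (i in seq_len(model$length))
    writeLines(paste("node", i, paste(num(model$node_pot[i, ]),
                                      collapse = ",")), con)
  for (i in seq_along(model$edge_pot))
    writeLines(paste("edge", i, paste(num(as.vector(model$edge_pot[[i]])),
                                      collapse = ",")), con)
  invisible(path)
}

#' @rdname write_maxent_model
#' @export
read_maxent_model <- function(path) {
  ln <- readLines(path)
  if (!startsWith(ln[1], "# gess maxent model v1"))
    stop("unrecognized model file version")
  kv <- strsplit(ln[-1], " ")
  get1 <- function(key) {
    hit <- vapply(kv, function(f) f[1] == key, logical(1))
    kv[[which(hit)[1]]][-1]
  }
  alphabet <- strsplit(get1("alphabet"), ",")[[1]]
  K <- length(alphabet)
  len <- as.integer(get1("length"))
  node <- matrix(0, len, K, dimnames = list(NULL, alphabet))
  edge <- vector("list", max(len - 1L, 0L))
  for (f in kv) {
    if (f[1] == "node") {
      node[as.integer(f[2]), ] <- as.numeric(strsplit(f[3], ",")[[1]])
    } else if (f[1] == "edge") {
      edge[[as.integer(f[2])]] <- matrix(
        as.numeric(strsplit(f[3], ",")[[1]]), K, K,
        dimnames = list(alphabet, alphabet))
    }
  }
  structure(list(kind = get1("kind"), length = len, alphabet = alphabet,
                 constraint_order = as.numeric(
                   strsplit(get1("constraint_order"), ",")[[1]]),
                 node_pot = node, edge_pot = edge,
                 logZ = as.numeric(get1("logZ")),
                 background = stats::setNames(
                   as.numeric(strsplit(get1("background"), ",")[[1]]),
                   alphabet),
                 n_signal = as.integer(get1("n_signal")),
                 marginal_error = NA_real_, iterations = NA_integer_),
            class = "maxent_model")
}
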