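# Shared fixtures (built once per test run) and independent oracles.

fixture_env <- new.env()

# The reference study community: 10 compositionally distinct genomes.
test_community <- function() {
  if (is.null(fixture_env$comm)) {
    spec <- community_spec(n_genomes = 10, genome_length = 1e5, seed = 42)
    genomes <- build_community(spec)
    fixture_env$comm <- list(
      spec = spec,
      genomes = genomes,
      refs4 = make_signatures(genomes, genus = genomes$genus, k = 4),
      refs6 = make_signatures(genomes, genus = genomes$genus, k = 6)
    )
  }
  fixture_env$comm
}

# N50/L50 oracle: explicit descending scan, no vectorised shortcuts.
oracle_n50_l50 <- function(lens) {
  sorted <- sort(lens, decreasing = TRUE)
  half <- sum(lens) / 2
  acc <- 0
  for (i in seq_along(sorted)) {
    acc <- acc + sorted[i]
    if (acc >= half) return(list(n50 = sorted[i], l50 = i))
  }
}

# NNLS oracle: exhaustive active-set enumeration (feasible for tiny p).
# For every support set, solve the unconstrained least squares restricted to
# it; keep solutions that are non-negative and satisfy the KKT condition
# that the gradient is non-negative outside the support; return the best.
oracle_nnls <- function(A, b, tol = 1e-9) {
  p <- ncol(A)
  best <- NULL
  best_rss <- Inf
  for (mask in 0:(2^p - 1)) {
    S <- which(bitwAnd(mask, 2^(0:(p - 1))) > 0)
    x <- numeric(p)
    if (length(S) > 0) {
      xs <- tryCatch(qr.solve(A[, S, drop = FALSE], b),
                     error = function(e) NULL)
      if (is.null(xs) || any(xs < -tol)) next
      x[S] <- pmax(xs, 0)
    }
    grad <- as.numeric(crossprod(A, A %*% x - b))
    if (any(grad[setdiff(seq_len(p), S)] < -1e-6)) next
    rss <- sum((A %*% x - b)^2)
    if (rss < best_rss - tol) {
      best_rss <- rss
      best <- x
    }
  }
  best
}

# Direct per-item diversity computation (loop form, no shared code paths).
oracle_diversity <- function(counts) {
  counts <- counts[counts > 0]
  S <- length(counts)
  N <- sum(counts)
  H <- 0
  D <- 0
  for (ni in counts) {
    p <- ni / N
    H <- H - p * log(p)
    D <- D + p^2
  }
  list(
    margalef = if (N == 1) 0 else (S - 1) / log(N),
    shannon = H,
    pielou = if (S == 1) NA_real_ else H / log(S),
    simpson_c = 1 - D
  )
}

rc <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
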