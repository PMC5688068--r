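# Small data builders shared across tests.

# A processed-style table (already centred/scaled-ish) built directly from
# Gaussian features: subject_id, group, V1..Vp. `shift` moves the first
# `n_shift` features in group 2.
make_processed <- function(n1 = 14, n2 = 11, p = 10, shift = 0, n_shift = 0,
                           seed = 1) {
  withr::with_seed(seed, {
    n <- n1 + n2
    X <- matrix(rnorm(n * p), n, p)
    if (n_shift > 0) {
      X[(n1 + 1):n, seq_len(n_shift)] <- X[(n1 + 1):n, seq_len(n_shift)] + shift
    }
    colnames(X) <- paste0("V", seq_len(p))
    dplyr::bind_cols(
      tibble::tibble(
        subject_id = sprintf("S%02d", seq_len(n)),
        group = factor(rep(c("NW", "OW/Ob"), c(n1, n2)),
                       levels = c("NW", "OW/Ob"))
      ),
      tibble::as_tibble(X)
    )
  })
}

# A tiny raw cohort table with explicit values for preprocessing tests.
make_raw_table <- function(values, subject_ids, groups, replicates = NULL) {
  meta <- tibble::tibble(
    subject_id = subject_ids,
    group = factor(groups, levels = c("NW", "OW/Ob"))
  )
  if (!is.null(replicates)) meta$replicate <- replicates
  dplyr::bind_cols(meta, tibble::as_tibble(values))
}

# Independent PLS1 oracle via the Krylov-subspace (Helland) formulation:
# B spans K = [s, M s, ..., M^{A-1} s] with s = X'y, M = X'X, and equals
# K (K' M K)^{-1} K' s. Algebraically equivalent to NIPALS PLS1 but computed
# by a wholly different route.
krylov_pls_b <- function(X, y, A) {
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  M <- crossprod(Xc)
  s <- crossprod(Xc, yc)
  K <- matrix(0, ncol(X), A)
  v <- s
  for (a in seq_len(A)) {
    K[, a] <- v
    v <- M %*% v
  }
  K %*% solve(t(K) %*% M %*% K, t(K) %*% s)
}

# Brute-force concordance AUC over all positive/negative pairs, ties 1/2.
brute_auc <- function(values, is_pos) {
  pos <- values[is_pos]
  neg <- values[!is_pos]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}
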