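# Independent oracles used to cross-check the implementation. These are
# deliberately naive (plain loops, closed forms, enumeration) and never call
# the code paths they verify.

# Brute-force nearest-focal distances: O(n * m) scan, one query at a time.
oracle_nearest <- function(qx, qy, rx, ry) {
  out <- numeric(length(qx))
  for (i in seq_along(qx)) {
    out[i] <- sqrt(min((qx[i] - rx)^2 + (qy[i] - ry)^2))
  }
  out
}

# Naive dense reimplementation of the module score, following the documented
# sampling protocol (seeded draw per program gene, in gene-set order, from
# the gene's equal-frequency expression bin) with scalar loops throughout.
oracle_score <- function(mat, genes, n_bins, n_ctrl, seed) {
  gid <- colnames(mat)
  means <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) means[j] <- mean(mat[, j])
  ord <- order(means, seq_along(means))
  sizes <- rep(ncol(mat) %/% n_bins, n_bins)
  if (ncol(mat) %% n_bins > 0) {
    sizes[seq_len(ncol(mat) %% n_bins)] <- sizes[seq_len(ncol(mat) %% n_bins)] + 1L
  }
  bins <- integer(ncol(mat)); bins[ord] <- rep(seq_len(n_bins), sizes)
  names(bins) <- gid
  present <- genes[genes %in% gid]
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  drawn <- list()
  for (gn in present) {
    cand <- gid[bins == bins[[gn]] & !(gid %in% present)]
    drawn[[gn]] <- sample(cand, n_ctrl, replace = length(cand) < n_ctrl)
  }
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, globalenv())
  pool <- unique(unlist(drawn))
  score <- numeric(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    score[i] <- mean(mat[i, present]) - mean(mat[i, pool])
  }
  score
}

# Closed-form one-way ANOVA.
oracle_anova <- function(groups) {
  k <- length(groups); n <- vapply(groups, length, 1L); N <- sum(n)
  gm <- mean(unlist(groups))
  ssb <- sum(n * (vapply(groups, mean, 1) - gm)^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 1))
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = f, p = stats::pf(f, k - 1, N - k, lower.tail = FALSE),
       mse = ssw / (N - k), df = N - k)
}

# Tukey HSD adjusted p for one pair, from the studentized range distribution.
oracle_tukey_p <- function(mi, mj, ni, nj, mse, k, df) {
  q <- abs(mi - mj) / sqrt(mse / 2 * (1 / ni + 1 / nj))
  stats::ptukey(q, k, df, lower.tail = FALSE)
}

# Welch two-tailed t-test, closed form.
oracle_welch <- function(a, b) {
  va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Exact two-sided rank-sum p by complete enumeration (no ties).
oracle_ranksum <- function(a, b) {
  stopifnot(!anyDuplicated(c(a, b)))
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(a)])
  combs <- utils::combn(length(pooled), length(a))
  w_all <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- length(a) * (length(pooled) + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# Pearson r and its t-distribution p, closed form.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# Independent refit oracle for the cell typer: full multinomial logistic
# regression with L2 penalty fitted by quasi-Newton optimisation, with the
# same stratified folds and strength grid; selects the strength by CV
# multinomial deviance and reports held-out accuracy.
oracle_multinom_fit <- function(x, y, lambda) {
  classes <- levels(y)
  K <- length(classes); G <- ncol(x); n <- nrow(x)
  ymat <- outer(y, classes, "==") * 1
  obj <- function(par) {
    B <- matrix(par, G + 1, K)
    eta <- cbind(1, x) %*% B
    eta <- eta - apply(eta, 1, max)
    logz <- log(rowSums(exp(eta)))
    ll <- sum(ymat * eta) - sum(logz)
    -ll / n + lambda / 2 * sum(B[-1, ]^2)
  }
  grad <- function(par) {
    B <- matrix(par, G + 1, K)
    eta <- cbind(1, x) %*% B
    eta <- eta - apply(eta, 1, max)
    p <- exp(eta) / rowSums(exp(eta))
    Gm <- -t(cbind(1, x)) %*% (ymat - p) / n
    Gm[-1, ] <- Gm[-1, ] + lambda * B[-1, ]
    as.numeric(Gm)
  }
  fit <- stats::optim(rep(0, (G + 1) * K), obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  matrix(fit$par, G + 1, K, dimnames = list(NULL, classes))
}

oracle_multinom_predict <- function(B, x) {
  eta <- cbind(1, x) %*% B
  colnames(B)[max.col(eta, ties.method = "first")]
}

oracle_multinom_cv <- function(x, y, foldid, grid) {
  y <- factor(y)
  dev <- vapply(sort(unique(grid), decreasing = TRUE), function(lam) {
    tot <- 0
    for (f in sort(unique(foldid))) {
      tr <- foldid != f
      B <- oracle_multinom_fit(x[tr, , drop = FALSE], droplevels(y[tr]), lam)
      eta <- cbind(1, x[!tr, , drop = FALSE]) %*% B
      eta <- eta - apply(eta, 1, max)
      p <- exp(eta) / rowSums(exp(eta))
      idx <- cbind(seq_len(sum(!tr)), match(y[!tr], colnames(B)))
      tot <- tot - 2 * sum(log(pmax(p[idx], 1e-12)))
    }
    tot
  }, numeric(1))
  lams <- sort(unique(grid), decreasing = TRUE)
  best <- lams[which.min(dev)]
  list(lambda = best, B = oracle_multinom_fit(x, y, best))
}

# Small deterministic lognorm-layer matrix for scoring tests.
toy_lognorm <- function(values, n_cells, n_genes,
                        cell_ids = sprintf("c%02d", seq_len(n_cells)),
                        gene_ids = sprintf("g%02d", seq_len(n_genes))) {
  count_matrix(matrix(values, n_cells, n_genes,
                      dimnames = list(cell_ids, gene_ids)),
               layer = "lognorm")
}

# Spatial fixtures: hand-placed or uniform maps with one focal type.
make_map <- function(x, y, types, sample_id = "s1", condition = NA) {
  n <- length(x)
  ids <- sprintf("%s_c%03d", sample_id, seq_len(n))
  list(map = data.frame(cell_id = ids, x_um = x, y_um = y,
                        sample_id = sample_id, stringsAsFactors = FALSE),
       cells = data.frame(cell_id = ids, sample_id = sample_id,
                          condition = condition, cell_type = types,
                          lineage = "other", stringsAsFactors = FALSE))
}

random_instance <- function(n, m, seed, sample_id = "s1", scale = 1000) {
  set.seed(seed)
  make_map(runif(n + m, 0, scale), runif(n + m, 0, scale),
           c(rep("other", n), rep("focal", m)), sample_id = sample_id)
}

# Lognorm reference whose classes express disjoint marker blocks.
separable_reference <- function(n_per_class = 60, n_genes = 30, seed = 11,
                                classes = c("A", "B")) {
  set.seed(seed)
  n <- n_per_class * length(classes)
  mu <- matrix(0.1, n, n_genes)
  block <- floor(n_genes / length(classes))
  for (k in seq_along(classes)) {
    rows <- (k - 1) * n_per_class + seq_len(n_per_class)
    cols <- (k - 1) * block + seq_len(block)
    mu[rows, cols] <- 5
  }
  counts <- matrix(rpois(n * n_genes, mu), n, n_genes,
                   dimnames = list(sprintf("c%04d", seq_len(n)),
                                   sprintf("g%03d", seq_len(n_genes))))
  list(m = normalize_counts(count_matrix(counts), norm_dialect("xenium")),
       labels = rep(classes, each = n_per_class))
}

# Forced five-cell QC toy: cells 2, 3 and 5 detect >= 100 genes and sit
# inside the [2000, 35000] total-count window; cell 1 is shallow, cell 4 too
# deep. Genes g111..g120 are detected only in removed cells.
toy_qc_matrix <- function() {
  n_genes <- 120
  m <- matrix(0, 5, n_genes,
              dimnames = list(sprintf("cell%d", 1:5),
                              sprintf("g%03d", seq_len(n_genes))))
  m[1, 1:5] <- 2                      # total 10, 5 genes
  m[2, 1:110] <- c(2391, rep(1, 109)) # total 2500, 110 genes
  m[3, 1:110] <- c(2491, rep(1, 109)) # total 2600, 110 genes
  m[4, 1:120] <- c(39881, rep(1, 119))# total 40000, 120 genes
  m[5, 1:110] <- c(1891, rep(1, 109)) # total 2000, 110 genes
  count_matrix(m)
}

# Random raw count_matrix fixture.
random_counts <- function(n, g, seed, lambda = 5) {
  set.seed(seed)
  x <- matrix(rpois(n * g, lambda), n, g,
              dimnames = list(sprintf("c%04d", seq_len(n)),
                              sprintf("g%04d", seq_len(g))))
  storage.mode(x) <- "double"   # readers return doubles; keep bitwise comparable
  count_matrix(x)
}
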