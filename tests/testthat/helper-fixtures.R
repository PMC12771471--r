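# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# one noiseless male elytron at the default geometry
noiseless_male <- function() fixture("noiseless_male", function()
  render_elytron(synthetic_elytron_config(sex = "male", noise_sd = 0,
                                          seed = 401)))

# small cohort (3 per sex) segmented and quantified end to end
small_quantified_cohort <- function() fixture("small_cohort", function() {
  coh <- render_cohort(3, seed = 402)
  meta <- data.frame(
    individual_id = vapply(coh, `[[`, "", "individual_id"),
    sex = toupper(substr(vapply(coh, `[[`, "", "sex"), 1, 1)),
    treatment = "GFP_RNAi")
  list(cohort = coh,
       result = quantify_cohort(lapply(coh, `[[`, "image"), meta))
})

# binary disk mask helper (independent rasterizer used as area oracle)
disk_mask <- function(H, W, cy, cx, r) {
  X <- matrix(rep(seq_len(W), each = H), H, W)
  Y <- matrix(rep(seq_len(H), times = W), H, W)
  (X - cx)^2 + (Y - cy)^2 <= r^2
}

ellipse_mask <- function(H, W, cy, cx, a, b, theta = 0) {
  X <- matrix(rep(seq_len(W), each = H), H, W)
  Y <- matrix(rep(seq_len(H), times = W), H, W)
  u <- cos(theta) * (X - cx) + sin(theta) * (Y - cy)
  v <- -sin(theta) * (X - cx) + cos(theta) * (Y - cy)
  (u / a)^2 + (v / b)^2 <= 1
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp_chr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# brute-force PSSM scanner: explicit per-window loops, both strands
brute_scan <- function(seq, mat, threshold) {
  bases <- strsplit(seq, "")[[1]]
  L <- ncol(mat)
  hits <- list()
  rc_rows <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq_len(length(bases) - L + 1)) {
    win <- bases[i:(i + L - 1)]
    if (any(!win %in% c("A", "C", "G", "T"))) next
    s_fwd <- 0; s_rev <- 0
    win_rc <- rev(rc_rows[win])
    for (j in seq_len(L)) {
      s_fwd <- s_fwd + mat[win[j], j]
      s_rev <- s_rev + mat[win_rc[j], j]
    }
    if (s_fwd >= threshold)
      hits[[length(hits) + 1]] <- data.frame(start = i - 1L, strand = "+",
                                             score = s_fwd)
    if (s_rev >= threshold)
      hits[[length(hits) + 1]] <- data.frame(start = i - 1L, strand = "-",
                                             score = s_rev)
  }
  if (length(hits) == 0)
    return(data.frame(start = integer(0), strand = character(0),
                      score = numeric(0)))
  out <- do.call(rbind, hits)
  out[order(out$start, out$strand), , drop = FALSE]
}

# brute-force Brunner-Munzel via explicit pairwise counts and rank loops
brute_bm <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  rk <- function(v, ref) vapply(v, function(z)
    sum(ref < z) + (sum(ref == z) + 1) / 2, numeric(1))
  r <- rk(pooled, pooled)
  r1 <- rk(x, x); r2 <- rk(y, y)
  m1 <- mean(r[1:n1]); m2 <- mean(r[n1 + 1:n2])
  p_hat <- mean(outer(x, y, function(a, b)
    (a < b) + 0.5 * (a == b)))
  v1 <- sum((r[1:n1] - r1 - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  v2 <- sum((r[n1 + 1:n2] - r2 - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  stat <- n1 * n2 * (m2 - m1) / (n1 + n2) / sqrt(n1 * v1 + n2 * v2)
  df <- (n1 * v1 + n2 * v2)^2 /
    ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1))
  list(p_hat = p_hat, statistic = stat, df = df,
       p_value = 2 * stats::pt(-abs(stat), df))
}
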