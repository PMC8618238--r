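# fixtures are built in code; no data files

# count_matrix from a bare matrix: sample ids "<group>_r<i>", equal lengths
make_cm <- function(counts, groups, lengths_bp = NULL, heat_shock = NULL) {
  ng <- nrow(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%03d", seq_len(ng))
  }
  reps <- stats::ave(seq_along(groups), groups, FUN = seq_along)
  ids <- paste0(groups, "_r", reps)
  colnames(counts) <- ids
  if (is.null(lengths_bp)) {
    lengths_bp <- stats::setNames(rep(1000, ng), rownames(counts))
  }
  if (is.null(heat_shock)) heat_shock <- rep(FALSE, length(groups))
  count_matrix(counts, lengths_bp,
               data.frame(sample_id = ids, group = groups, replicate = reps,
                          heat_shock = heat_shock,
                          rnai_target = "EV", stringsAsFactors = FALSE))
}

# 5 genes x 4 samples, two groups, deterministic values
tiny_cm <- function() {
  m <- matrix(c(10, 12, 5, 6,
                100, 90, 110, 95,
                0, 0, 3, 4,
                7, 0, 7, 8,
                55, 60, 20, 25), nrow = 5, byrow = TRUE)
  make_cm(m, c("A", "A", "B", "B"),
          lengths_bp = stats::setNames(c(500, 1000, 2000, 1500, 800),
                                       sprintf("g%03d", 1:5)))
}

# hand-coded unpooled two-proportion z-test on pooled group counts
pooled_z_oracle <- function(yt, nt, yb, nb) {
  pt <- sum(yt) / sum(nt)
  pb <- sum(yb) / sum(nb)
  (pt - pb) / sqrt(pt * (1 - pt) / sum(nt) + pb * (1 - pb) / sum(nb))
}

# brute-force hypergeometric upper tail by pmf summation (oracle for tiny N)
hyper_sf_oracle <- function(k, m, n, N) {
  i <- k:min(m, n)
  sum(choose(m, i) * choose(N - m, n - i)) / choose(N, n)
}
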