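# Shared fixtures and independent oracles for the test suite.

identity_scheme <- function() {
  raac_scheme(paste(AA_CANONICAL, collapse = "-"))
}

# Random canonical protein sequences (uniform background unless freqs given).
random_proteins <- function(n, len_range = c(30, 60), freqs = NULL,
                            prefix = "s") {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(AA_CANONICAL, L, replace = TRUE, prob = freqs),
          collapse = "")
  }, character(1))
  setNames(seqs, paste0(prefix, seq_len(n)))
}

# A plain feature table (label + numeric columns) for selection/model tests
# that do not need a real sequence encoding behind it.
toy_features <- function(x, y, prefix = "f") {
  colnames(x) <- paste0(prefix, seq_len(ncol(x)))
  dplyr::bind_cols(
    tibble::tibble(sample_id = paste0("s", seq_len(nrow(x))),
                   label = as.integer(y)),
    tibble::as_tibble(as.data.frame(x))
  )
}

# Two well-separated Gaussian clusters in d dimensions.
separable_clusters <- function(n_per_class = 30, d = 5, gap = 6, sd = 1) {
  x <- rbind(
    matrix(stats::rnorm(n_per_class * d, mean = gap / 2, sd = sd),
           n_per_class, d),
    matrix(stats::rnorm(n_per_class * d, mean = -gap / 2, sd = sd),
           n_per_class, d)
  )
  toy_features(x, rep(c(1L, 0L), each = n_per_class))
}

# Independent brute-force one-way two-group ANOVA F, written directly from
# the textbook sums of squares (kept deliberately separate from the package
# routine).
brute_force_f <- function(values, labels) {
  g1 <- values[labels == 1]
  g0 <- values[labels == 0]
  grand <- mean(values)
  ss_between <- length(g1) * (mean(g1) - grand)^2 +
    length(g0) * (mean(g0) - grand)^2
  ss_within <- sum((g1 - mean(g1))^2) + sum((g0 - mean(g0))^2)
  df_between <- 1
  df_within <- length(values) - 2
  (ss_between / df_between) / (ss_within / df_within)
}

# Trapezoidal area under the ROC polygon, the independent companion to the
# rank-statistic AUC.
trapezoid_auc <- function(points) {
  pts <- points[order(points$fpr, points$tpr), ]
  sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
}

# Count k-mers of a raw sequence, mapping each window through the scheme --
# the "count then map" oracle for the encoding equivalence property.
count_then_map <- function(seq, scheme, k) {
  L <- nchar(seq)
  windows <- substring(seq, 1:(L - k + 1), k:L)
  map <- setNames(rep(scheme$representatives, lengths(scheme$groups)),
                  unlist(scheme$groups))
  mapped <- vapply(strsplit(windows, ""), function(ch) {
    paste(map[ch], collapse = "")
  }, character(1))
  nm <- kmer_names(scheme, k)
  counts <- table(factor(mapped, levels = nm))
  as.vector(counts) / (L - k + 1)
}
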