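#' K-mer names for a (scheme, k) encoding
#'
#' All `size^k` words of length `k` over the scheme's representative letters,
#' ordered lexicographically in group order (first position most
#' significant). This fixed ordering defines the feature columns everywhere
#' in the package.
#'
#' @param scheme An [raac_scheme].
#' @param k K-mer order, 1--3.
#' @return Character vector of length `scheme$size^k`.
#' @export
kmer_names <- function(scheme, k) {
  k <- check_k(k)
  reps <- scheme$representatives
  grid <- expand.grid(rep(list(reps), k), stringsAsFactors = FALSE)
  do.call(paste0, rev(grid))
}

check_k <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || k != as.integer(k) || k < 1 ||
      k > 3) {
    abort("k must be 1, 2 or 3", class = "raacpred_error_bad_k")
  }
  as.integer(k)
}

#' K-mer composition of a reduced sequence
#'
#' Counts the `L - k + 1` overlapping k-mers of a sequence already written
#' over the scheme's reduced alphabet and normalizes by the window count, so
#' the result is a frequency vector summing to 1.
#'
#' @param rseq A reduced sequence string (over the scheme's representative
#'   letters, e.g. from [reduce_sequence()]).
#' @param scheme The [raac_scheme] the sequence was reduced with.
#' @param k K-mer order, 1--3.
#' @return Named numeric vector of length `scheme$size^k` (names from
#'   [kmer_names()]).
#' @examples
#' sch <- raac_scheme("A-C-D-E-F-G-H-I-K-L-M-N-P-Q-R-S-T-V-W-Y")
#' kmer_composition("ACAC", sch, k = 2)[c("AC", "CA")]
#' @export
kmer_composition <- function(rseq, scheme, k) {
  k <- check_k(k)
  L <- nchar(rseq)
  if (L < k) {
    abort(paste0("Sequence of length ", L, " is shorter than k = ", k),
          class = "raacpred_error_too_short")
  }
  nm <- kmer_names(scheme, k)
  windows <- substring(rseq, 1:(L - k + 1), k:L)
  counts <- tabulate(factor(windows, levels = nm), nbins = length(nm))
  setNames(counts / (L - k + 1), nm)
}

#' Encode a labelled two-class sequence set as a k-mer feature table
#'
#' The core encoding step: each sequence is rewritten over the reduced
#' alphabet and summarized by its k-mer composition. Positives come first,
#' then negatives, with a binary `label` column (1 = positive, 0 =
#' negative). Sequences shorter than `k` after reduction are skipped and
#' counted.
#'
#' @param pos,neg Positive- and negative-class sequences; each may be a FASTA
#'   path or any input accepted by [reduce_sequences()].
#' @param scheme An [raac_scheme].
#' @param k K-mer order, 1--3.
#' @param nonstandard Policy for non-canonical residues, see
#'   [reduce_sequences()].
#' @return A tibble of class `raac_features` with columns `sample_id`,
#'   `label` (integer 1/0) and one numeric column per k-mer. Attributes:
#'   `scheme`, `k`, `feature_names`, `skipped` (tibble of skipped sequence
#'   ids and reasons).
#' @examples
#' sch <- raac_type33()[["2"]]
#' encode_dataset(c(p = "CWCW"), c(n = "AAAA"), sch, k = 1)
#' @export
encode_dataset <- function(pos, neg, scheme, k,
                           nonstandard = c("drop", "error")) {
  nonstandard <- match.arg(nonstandard)
  pos_tbl <- encode_sequences(as_fasta_or_seqs(pos), scheme, k, nonstandard)
  neg_tbl <- encode_sequences(as_fasta_or_seqs(neg), scheme, k, nonstandard)
  for (cls in c("pos", "neg")) {
    tbl <- if (cls == "pos") pos_tbl else neg_tbl
    if (nrow(tbl) == 0) {
      abort(paste0("All ", cls, " sequences were skipped (shorter than k)"),
            class = "raacpred_error_empty_class")
    }
  }
  out <- dplyr::bind_rows(
    dplyr::mutate(pos_tbl, label = 1L, .after = "sample_id"),
    dplyr::mutate(neg_tbl, label = 0L, .after = "sample_id")
  )
  skipped <- dplyr::bind_rows(
    dplyr::mutate(attr(pos_tbl, "skipped"), class = "pos"),
    dplyr::mutate(attr(neg_tbl, "skipped"), class = "neg")
  )
  new_raac_features(out, scheme, k, skipped)
}

#' Encode sequences (single class) as k-mer composition rows
#'
#' @inheritParams encode_dataset
#' @param x Sequences (FASTA path or any input accepted by
#'   [reduce_sequences()]).
#' @return A tibble with `sample_id` plus one column per k-mer; attribute
#'   `skipped` records sequences shorter than `k`.
#' @export
encode_sequences <- function(x, scheme, k,
                             nonstandard = c("drop", "error")) {
  k <- check_k(k)
  nonstandard <- match.arg(nonstandard)
  reduced <- reduce_sequences(as_fasta_or_seqs(x), scheme, nonstandard)
  too_short <- nchar(reduced$sequence) < k
  skipped <- tibble::tibble(
    id = reduced$id[too_short],
    reason = rep("shorter than k", sum(too_short))
  )
  kept <- reduced[!too_short, ]
  nm <- kmer_names(scheme, k)
  rows <- lapply(kept$sequence, kmer_composition, scheme = scheme, k = k)
  mat <- if (length(rows) > 0) do.call(rbind, rows) else
    matrix(numeric(0), 0, length(nm), dimnames = list(NULL, nm))
  out <- tibble::as_tibble(as.data.frame(mat, check.names = FALSE))
  out <- dplyr::bind_cols(tibble::tibble(sample_id = kept$id), out)
  attr(out, "skipped") <- skipped
  out
}

new_raac_features <- function(tbl, scheme, k, skipped) {
  structure(
    tbl,
    scheme = scheme,
    k = k,
    feature_names = kmer_names(scheme, k),
    skipped = skipped,
    class = c("raac_features", class(tbl))
  )
}

#' Extract the numeric feature matrix and labels from a feature table
#'
#' @param data A feature tibble from [encode_dataset()] (or any data frame
#'   with `label` plus numeric feature columns).
#' @return A list with `x` (numeric matrix), `y` (integer labels) and
#'   `sample_id`.
#' @export
features_matrix <- function(data) {
  stopifnot(is.data.frame(data), "label" %in% names(data))
  meta <- intersect(c("sample_id", "label"), names(data))
  x <- as.matrix(data[setdiff(names(data), meta)])
  storage.mode(x) <- "double"
  list(
    x = x,
    y = as.integer(data$label),
    sample_id = if ("sample_id" %in% names(data)) data$sample_id
                else as.character(seq_len(nrow(data)))
  )
}

#' Write / read a feature table as TSV
#'
#' The header row carries the k-mer names; `sample_id` and `label` columns
#' are preserved. Numeric values round-trip at full precision.
#'
#' @param data Feature tibble.
#' @param path Output path.
#' @return `path` (writer) or a tibble (reader), invisibly for the writer.
#' @export
write_features_tsv <- function(data, path) {
  df <- as.data.frame(data, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_tsv
#' @export
read_features_tsv <- function(path) {
  tibble::as_tibble(
    read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
               stringsAsFactors = FALSE)
  )
}

# A character scalar that names an existing file is treated as a FASTA path;
# everything else passes through to the sequence coercers.
as_fasta_or_seqs <- function(x) {
  if (is.character(x) && length(x) == 1 && is.null(names(x)) &&
      file.exists(x)) {
    return(read_fasta(x))
  }
  x
}
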