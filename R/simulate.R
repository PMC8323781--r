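# Polar residues used for the composition tilt of positive sequences; the
# complement is the hydrophobic/aromatic set. Mirrors the coarsest
# polar/hydrophobic split exploited by the type-33 alphabets.
POLAR_RESIDUES <- c("S", "T", "A", "N", "D", "G", "R", "Q", "E", "K", "H", "P")

#' Configuration for the synthetic two-class sequence generator
#'
#' The generator emulates the statistical structure a family classifier
#' exploits in a real metal-binding enzyme family: positive sequences carry
#' one instance of a conserved catalytic motif (by default the
#' 2-His-1-carboxylate `H-x-D ... H` iron-binding triad) on a background
#' whose composition is tilted toward polar residues; negative sequences
#' are background only.
#'
#' @param n_pos,n_neg Number of positive / negative sequences (default
#'   240 each, the training-set scale of a curated two-class family
#'   benchmark).
#' @param length_range Integer (min, max) sequence length; lengths are
#'   uniform on this range.
#' @param motif Character vector of motif segments; within a segment each
#'   letter is literal except `x`, which matches any canonical residue.
#'   Consecutive segments are separated by a background spacer whose length
#'   is uniform on `spacer_range`.
#' @param spacer_range Integer (min, max) spacer length between motif
#'   segments.
#' @param background_freqs Named length-20 probability vector over
#'   [AA_CANONICAL] (default uniform, which keeps background motif-match
#'   rates analytically simple).
#' @param positive_bias Mixing weight in \[0, 1\]: positive backgrounds are
#'   drawn from `(1 - bias) * background + bias * polar`, where `polar` is
#'   uniform over the 12 polar residues. 0 removes the composition signal.
#' @param motif_noise Per-position substitution probability applied to the
#'   literal motif positions in positives; 1 destroys the motif signal.
#' @param seed Integer seed; the generator is bit-reproducible under it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_pos = 240L, n_neg = 240L,
                       length_range = c(120L, 300L),
                       motif = c("HxD", "H"),
                       spacer_range = c(10L, 40L),
                       background_freqs = NULL,
                       positive_bias = 0.25,
                       motif_noise = 0.1,
                       seed = 1L) {
  background_freqs <- background_freqs %||%
    setNames(rep(1 / 20, 20), AA_CANONICAL)
  stopifnot(
    n_pos >= 1, n_neg >= 1,
    length(length_range) == 2, length_range[1] <= length_range[2],
    length(spacer_range) == 2, 0 <= spacer_range[1],
    spacer_range[1] <= spacer_range[2],
    positive_bias >= 0, positive_bias <= 1,
    motif_noise >= 0, motif_noise <= 1
  )
  if (!setequal(names(background_freqs), AA_CANONICAL) ||
      abs(sum(background_freqs) - 1) > 1e-8 || any(background_freqs < 0)) {
    abort("background_freqs must be a probability vector over the 20 canonical amino acids",
          class = "raacpred_error_bad_freqs")
  }
  span_max <- motif_span(motif, spacer_range[2])
  if (length_range[1] < span_max) {
    abort(paste0("Minimum length ", length_range[1],
                 " is below the maximum motif span ", span_max),
          class = "raacpred_error_infeasible_motif")
  }
  structure(
    list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
         length_range = as.integer(length_range), motif = toupper(motif),
         spacer_range = as.integer(spacer_range),
         background_freqs = background_freqs[AA_CANONICAL],
         positive_bias = positive_bias, motif_noise = motif_noise,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

motif_span <- function(motif, spacer_len) {
  sum(nchar(motif)) + spacer_len * (length(motif) - 1)
}

#' Generate a synthetic two-class protein sequence dataset
#'
#' Positives are background sequences with one noisy motif instance
#' written in at a uniformly random feasible position and a composition
#' tilted toward polar residues; negatives are pure background. Output is
#' standard FASTA plus a plain-text truth manifest recording each
#' sequence's label and motif start.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed; default a fresh temp
#'   directory).
#' @return An object of class `raac_sim`: list with `pos_fasta`,
#'   `neg_fasta`, `manifest_path`, `manifest` (tibble `id`, `label`,
#'   `length`, `motif_start`) and `config`. Identical configs (including
#'   seed) produce byte-identical files.
#' @examples
#' sim <- simulate_dataset(sim_config(n_pos = 3, n_neg = 3, seed = 7))
#' sim$manifest
#' @export
simulate_dataset <- function(config = sim_config(), dir = tempfile("raacsim")) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pos_bg <- (1 - config$positive_bias) * config$background_freqs +
    config$positive_bias *
      setNames(as.numeric(AA_CANONICAL %in% POLAR_RESIDUES) /
                 length(POLAR_RESIDUES), AA_CANONICAL)

  with_seed(config$seed, {
    lens_pos <- sample_range(config$length_range, config$n_pos)
    lens_neg <- sample_range(config$length_range, config$n_neg)
    pos <- lapply(lens_pos, random_sequence, freqs = pos_bg)
    starts <- integer(config$n_pos)
    for (i in seq_len(config$n_pos)) {
      ins <- instantiate_motif(config)
      span <- length(ins$letters)
      starts[i] <- sample.int(lens_pos[i] - span + 1, 1)
      pos[[i]][starts[i]:(starts[i] + span - 1)] <- ins$letters
    }
    neg <- lapply(lens_neg, random_sequence,
                  freqs = config$background_freqs)
  })

  pos_seqs <- setNames(vapply(pos, paste, character(1), collapse = ""),
                       sprintf("pos_%04d", seq_len(config$n_pos)))
  neg_seqs <- setNames(vapply(neg, paste, character(1), collapse = ""),
                       sprintf("neg_%04d", seq_len(config$n_neg)))
  pos_fasta <- file.path(dir, "positives.fasta")
  neg_fasta <- file.path(dir, "negatives.fasta")
  write_fasta(pos_seqs, pos_fasta)
  write_fasta(neg_seqs, neg_fasta)

  manifest <- tibble::tibble(
    id = c(names(pos_seqs), names(neg_seqs)),
    label = rep(c(1L, 0L), c(config$n_pos, config$n_neg)),
    length = c(lens_pos, lens_neg),
    motif_start = c(starts, rep(NA_integer_, config$n_neg))
  )
  manifest_path <- file.path(dir, "manifest.tsv")
  write.table(as.data.frame(manifest), manifest_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  structure(
    list(pos_fasta = pos_fasta, neg_fasta = neg_fasta,
         manifest_path = manifest_path, manifest = manifest,
         config = config),
    class = "raac_sim"
  )
}

#' @export
print.raac_sim <- function(x, ...) {
  cat("<raac_sim>", x$config$n_pos, "positives +", x$config$n_neg,
      "negatives in", dirname(x$pos_fasta), "\n")
  invisible(x)
}

random_sequence <- function(len, freqs) {
  sample(AA_CANONICAL, len, replace = TRUE, prob = freqs)
}

# Uniform draw from an integer range given as c(lo, hi); immune to the
# sample() scalar expansion when lo == hi.
sample_range <- function(range, n) {
  vals <- range[1]:range[2]
  vals[sample.int(length(vals), n, replace = TRUE)]
}

# Draw one motif instance as a letter vector: literals kept (then hit by
# motif_noise), 'x' positions and spacers drawn from the background.
instantiate_motif <- function(config) {
  segs <- config$motif
  letters_out <- character(0)
  literal_pos <- logical(0)
  for (i in seq_along(segs)) {
    if (i > 1) {
      ell <- sample_range(config$spacer_range, 1)
      letters_out <- c(letters_out,
                       random_sequence(ell, config$background_freqs))
      literal_pos <- c(literal_pos, rep(FALSE, ell))
    }
    chars <- strsplit(segs[i], "")[[1]]
    for (ch in chars) {
      if (ch == "X") {
        letters_out <- c(letters_out, sample(AA_CANONICAL, 1))
        literal_pos <- c(literal_pos, FALSE)
      } else {
        letters_out <- c(letters_out, ch)
        literal_pos <- c(literal_pos, TRUE)
      }
    }
  }
  if (config$motif_noise > 0) {
    hit <- literal_pos & stats::runif(length(letters_out)) < config$motif_noise
    if (any(hit)) {
      letters_out[hit] <- sample(AA_CANONICAL, sum(hit), replace = TRUE)
    }
  }
  list(letters = letters_out, literal = literal_pos)
}

#' Count motif matches in sequences
#'
#' Counts, for each sequence, the number of (start, spacer-length) windows
#' that exactly match the motif grammar (`x` = any canonical letter; spacer
#' length swept over `spacer_range`). Overlapping matches all count, which
#' makes the expected count under a uniform background exactly
#' `sum_l (L - span(l) + 1) * p_literal`, with `p_literal` the product of
#' per-literal match probabilities.
#'
#' @param seqs Character vector of sequences.
#' @param motif Motif segments as in [sim_config()].
#' @param spacer_range Integer (min, max) spacer length.
#' @return Integer vector of match counts, one per sequence.
#' @export
count_motif_matches <- function(seqs, motif = c("HxD", "H"),
                                spacer_range = c(10L, 40L)) {
  motif <- toupper(motif)
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  Lmax <- max(lens)
  # pad to a rectangular letter matrix; pads never match a literal
  m <- matrix(".", nrow = length(seqs), ncol = Lmax)
  sp <- strsplit(seqs, "")
  for (i in seq_along(sp)) m[i, seq_len(lens[i])] <- sp[[i]]

  counts <- integer(length(seqs))
  for (ell in spacer_range[1]:spacer_range[2]) {
    req <- motif_literal_offsets(motif, ell)
    span <- motif_span(motif, ell)
    if (span > Lmax) next
    n_starts <- Lmax - span + 1
    ok <- matrix(TRUE, nrow = length(seqs), ncol = n_starts)
    for (j in seq_len(nrow(req))) {
      cols <- (1 + req$offset[j]):(n_starts + req$offset[j])
      ok <- ok & (m[, cols, drop = FALSE] == req$letter[j])
    }
    # starts running past a sequence's true end are impossible (pads don't
    # match), so row sums are correct per sequence
    counts <- counts + as.integer(rowSums(ok))
  }
  counts
}

# (offset, letter) constraints of the motif for a given spacer length;
# offsets are 0-based from the match start.
motif_literal_offsets <- function(motif, spacer_len) {
  offset <- integer(0); letter <- character(0)
  pos <- 0L
  for (i in seq_along(motif)) {
    if (i > 1) pos <- pos + spacer_len
    chars <- strsplit(motif[i], "")[[1]]
    for (ch in chars) {
      if (ch != "X") {
        offset <- c(offset, pos)
        letter <- c(letter, ch)
      }
      pos <- pos + 1L
    }
  }
  data.frame(offset = offset, letter = letter)
}

#' Expected motif match count under a uniform background
#'
#' Closed form companion to [count_motif_matches()]: for a sequence of
#' length `L` over a uniform 20-letter background, the expected number of
#' matching (start, spacer) windows is
#' `sum_l max(0, L - span(l) + 1) * (1/20)^n_literal`.
#'
#' @param L Sequence length (vectorized).
#' @inheritParams count_motif_matches
#' @return Numeric vector of expected counts.
#' @export
expected_motif_matches <- function(L, motif = c("HxD", "H"),
                                   spacer_range = c(10L, 40L)) {
  motif <- toupper(motif)
  n_literal <- sum(vapply(strsplit(motif, ""), function(ch) sum(ch != "X"),
                          integer(1)))
  p <- (1 / 20)^n_literal
  vapply(L, function(len) {
    sum(vapply(spacer_range[1]:spacer_range[2], function(ell) {
      max(0, len - motif_span(motif, ell) + 1) * p
    }, numeric(1)))
  }, numeric(1))
}

#' Greedy sequence-identity filter
#'
#' A deliberately simple redundancy filter: sequences are taken in input
#' order and each is kept only if its ungapped identity to every
#' already-kept sequence is below `threshold`. Identity is the fraction
#' of matching positions over the length of the shorter sequence, with no
#' alignment — an approximation of clustering-based redundancy removal
#' (CD-HIT style), not a reimplementation of it.
#'
#' @param x Sequences: FASTA path or any input accepted by
#'   [reduce_sequences()].
#' @param threshold Identity cutoff in (0, 1]: a sequence is removed when
#'   its identity to a kept sequence reaches the cutoff, so at 1 only exact
#'   (prefix-identical) duplicates are removed.
#' @param output Optional path; if given, the retained sequences are
#'   written there as FASTA.
#' @return A tibble `id`, `sequence`, `kept` (logical) for all inputs, in
#'   input order; attribute `kept_ids` for convenience.
#' @export
identity_filter <- function(x, threshold, output = NULL) {
  stopifnot(threshold > 0, threshold <= 1)
  seqs <- as_fasta_or_seqs(x)
  seqs <- as_named_sequences(seqs)
  n <- length(seqs)
  chars <- strsplit(toupper(unname(seqs)), "")
  kept <- logical(n)
  kept_idx <- integer(0)
  for (i in seq_len(n)) {
    redundant <- FALSE
    for (j in kept_idx) {
      len <- min(length(chars[[i]]), length(chars[[j]]))
      ident <- sum(chars[[i]][seq_len(len)] == chars[[j]][seq_len(len)]) / len
      if (ident >= threshold) { redundant <- TRUE; break }
    }
    if (!redundant) { kept[i] <- TRUE; kept_idx <- c(kept_idx, i) }
  }
  out <- tibble::tibble(id = names(seqs), sequence = unname(seqs),
                        kept = kept)
  if (!is.null(output)) {
    write_fasta(setNames(out$sequence[out$kept], out$id[out$kept]), output)
  }
  structure(out, kept_ids = out$id[out$kept])
}
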