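#' Parse a reduced amino acid alphabet (RAAC scheme)
#'
#' A reduction scheme partitions the 20 canonical amino acids into `s`
#' ordered, disjoint groups; sequences rewritten over the reduced alphabet use
#' one representative letter per group. Schemes are written in the standard
#' dash-delimited notation, e.g. `"S-T-A-N-D-G-RQ-EK-H-P-IV-L-M-WYF-C"` for a
#' 15-group alphabet: each dash-separated run of letters is one group.
#'
#' The representative of a group is its first listed letter, so reduction is
#' deterministic and follows the printed group order.
#'
#' @param spec Dash-delimited group string covering each canonical amino acid
#'   exactly once.
#' @param type_id Integer tag identifying the reduction method family the
#'   scheme belongs to (RAACBook-style type index, 1--74). Default 0 for ad
#'   hoc schemes.
#' @param size_hint Optional integer; if given, parsing fails unless the
#'   scheme has exactly this many groups.
#'
#' @return An object of class `raac_scheme`: a list with elements `type_id`,
#'   `size`, `groups` (list of character vectors), `representatives`
#'   (character vector, one per group) and `spec` (the input string,
#'   uppercased).
#'
#' @examples
#' sch <- raac_scheme("S-T-A-N-D-G-RQ-EK-H-P-IV-L-M-WYF-C", type_id = 33)
#' sch$size
#' sch$representatives
#' @export
raac_scheme <- function(spec, type_id = 0L, size_hint = NULL) {
  stopifnot(is.character(spec), length(spec) == 1L)
  spec <- toupper(trimws(spec))
  bad <- setdiff(unique(strsplit(gsub("-", "", spec), "")[[1]]), AA_CANONICAL)
  if (length(bad) > 0) {
    abort(
      paste0("Scheme contains non-canonical letter(s): ",
             paste(bad, collapse = ", ")),
      class = "raacpred_error_bad_letter"
    )
  }
  raw_groups <- strsplit(spec, "-", fixed = TRUE)[[1]]
  empty <- which(nchar(raw_groups) == 0)
  if (length(empty) > 0 || grepl("^-|-$", spec)) {
    abort(
      paste0("Empty group at position ", paste(empty, collapse = ", ")),
      class = "raacpred_error_empty_group"
    )
  }
  groups <- strsplit(raw_groups, "")
  flat <- unlist(groups)
  dup <- unique(flat[duplicated(flat)])
  if (length(dup) > 0) {
    abort(
      paste0("Letter(s) assigned to more than one group: ",
             paste(dup, collapse = ", ")),
      class = "raacpred_error_duplicate_letter"
    )
  }
  missing <- setdiff(AA_CANONICAL, flat)
  if (length(missing) > 0) {
    abort(
      paste0("Scheme does not cover letter(s): ",
             paste(missing, collapse = ", ")),
      class = "raacpred_error_missing_letter"
    )
  }
  if (!is.null(size_hint) && length(groups) != size_hint) {
    abort(
      paste0("Scheme has ", length(groups), " groups but size_hint = ",
             size_hint),
      class = "raacpred_error_size_mismatch"
    )
  }
  structure(
    list(
      type_id = as.integer(type_id),
      size = length(groups),
      groups = groups,
      representatives = vapply(groups, `[[`, character(1), 1L),
      spec = spec
    ),
    class = "raac_scheme"
  )
}

#' @export
print.raac_scheme <- function(x, ...) {
  cat("<raac_scheme> type ", x$type_id, ", size ", x$size, "\n  ",
      x$spec, "\n", sep = "")
  invisible(x)
}

#' @export
format.raac_scheme <- function(x, ...) x$spec

# Strings of the 18 nested type-33 reduction alphabets (sizes 2-19), derived
# from substitution-score clustering of aligned protein structures; the
# coarsest split separates the hydrophobic and polar groups.
.type33_specs <- c(
  "2"  = "STANDGRQEKHPIVLMWYF-C",
  "3"  = "STANDGRQEKHP-IVLMWYF-C",
  "4"  = "STANDG-RQEKHP-IVLMWYF-C",
  "5"  = "STAND-G-RQEKHP-IVLMWYF-C",
  "6"  = "STAND-G-RQEK-HP-IVLMWYF-C",
  "7"  = "STA-ND-G-RQEK-HP-IVLMWYF-C",
  "8"  = "STA-ND-G-RQ-EK-HP-IVLMWYF-C",
  "9"  = "STA-ND-G-RQ-EK-HP-IVLM-WYF-C",
  "10" = "ST-A-ND-G-RQ-EK-HP-IVLM-WYF-C",
  "11" = "ST-A-ND-G-RQ-EK-H-P-IVLM-WYF-C",
  "12" = "ST-A-N-D-G-RQ-EK-H-P-IVLM-WYF-C",
  "13" = "ST-A-N-D-G-RQ-EK-H-P-IV-LM-WYF-C",
  "14" = "S-T-A-N-D-G-RQ-EK-H-P-IV-LM-WYF-C",
  "15" = "S-T-A-N-D-G-RQ-EK-H-P-IV-L-M-WYF-C",
  "16" = "S-T-A-N-D-G-RQ-E-K-H-P-IV-L-M-WYF-C",
  "17" = "S-T-A-N-D-G-RQ-E-K-H-P-IV-L-M-WY-F-C",
  "18" = "S-T-A-N-D-G-R-Q-E-K-H-P-IV-L-M-WY-F-C",
  "19" = "S-T-A-N-D-G-R-Q-E-K-H-P-I-V-L-M-WY-F-C"
)

#' Built-in type-33 reduction schemes
#'
#' The 18 reduction alphabets of RAACBook type 33, one per size 2--19. They
#' form a nested hierarchy: every group of a finer scheme is contained in a
#' group of every coarser one. Type 33 groups amino acids by substitution
#' scores from aligned protein structures and at its coarsest separates
#' polar from hydrophobic residues, which is why it suits families (such as
#' the 2OG oxygenases) whose signal is a conserved polar metal-binding core.
#'
#' @return A named list of 18 [raac_scheme] objects; names are the sizes
#'   `"2"` ... `"19"`.
#' @examples
#' schemes <- raac_type33()
#' schemes[["15"]]
#' @export
raac_type33 <- function() {
  lapply(setNames(seq_along(.type33_specs), names(.type33_specs)), function(i) {
    raac_scheme(.type33_specs[[i]], type_id = 33L,
                size_hint = as.integer(names(.type33_specs)[i]))
  })
}

#' Does one scheme refine another?
#'
#' `fine` refines `coarse` when every group of `fine` is a subset of some
#' group of `coarse` (i.e. `coarse` can be obtained by merging groups of
#' `fine`). The built-in type-33 family is nested in this sense.
#'
#' @param fine,coarse [raac_scheme] objects.
#' @return Logical scalar.
#' @export
scheme_refines <- function(fine, coarse) {
  stopifnot(inherits(fine, "raac_scheme"), inherits(coarse, "raac_scheme"))
  all(vapply(fine$groups, function(g) {
    any(vapply(coarse$groups, function(h) all(g %in% h), logical(1)))
  }, logical(1)))
}

#' Read a scheme library file
#'
#' A scheme library is a plain-text registry of reduction schemes, one per
#' line, in the form `type <t> size <s> scheme <spec>`; blank lines and lines
#' starting with `#` are ignored. Keys `(type, size)` must be unique.
#'
#' @param path Path to a scheme library file.
#' @return A tibble with columns `type_id`, `size`, `spec` and a list-column
#'   `scheme` of validated [raac_scheme] objects, one row per registry entry.
#' @seealso [write_scheme_library()] for the exact-round-trip writer.
#' @export
read_scheme_library <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  entries <- lapply(keep, function(i) {
    m <- regmatches(
      lines[i],
      regexec("^\\s*type\\s+(\\d+)\\s+size\\s+(\\d+)\\s+scheme\\s+(\\S+)\\s*$",
              lines[i])
    )[[1]]
    if (length(m) != 4) {
      abort(paste0("Malformed scheme line ", i, ": ", lines[i]),
            class = "raacpred_error_malformed_line")
    }
    t <- as.integer(m[2]); s <- as.integer(m[3])
    list(type_id = t, size = s,
         scheme = raac_scheme(m[4], type_id = t, size_hint = s))
  })
  tb <- tibble::tibble(
    type_id = vapply(entries, `[[`, integer(1), "type_id"),
    size = vapply(entries, `[[`, integer(1), "size"),
    spec = vapply(entries, function(e) e$scheme$spec, character(1)),
    scheme = lapply(entries, `[[`, "scheme")
  )
  key <- paste(tb$type_id, tb$size)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    abort(paste0("Duplicate scheme key (type size): ", d),
          class = "raacpred_error_duplicate_key")
  }
  tb
}

#' Write a scheme library file
#'
#' Inverse of [read_scheme_library()]; re-reading the written file reproduces
#' the registry exactly.
#'
#' @param registry Tibble as returned by [read_scheme_library()], or a list of
#'   [raac_scheme] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scheme_library <- function(registry, path) {
  if (!is.data.frame(registry)) {
    registry <- tibble::tibble(
      type_id = vapply(registry, `[[`, integer(1), "type_id"),
      size = vapply(registry, `[[`, integer(1), "size"),
      spec = vapply(registry, `[[`, character(1), "spec")
    )
  }
  writeLines(
    sprintf("type %d size %d scheme %s",
            registry$type_id, registry$size, registry$spec),
    path
  )
  invisible(path)
}

#' Rewrite protein sequences over a reduced alphabet
#'
#' Each canonical residue is replaced by the representative letter of its
#' group. Input is case-insensitive. Non-canonical letters (B, J, O, U, X, Z
#' and the stop symbol `*`) are handled by `nonstandard`: `"drop"` (default)
#' removes them and reports how many were removed per sequence; `"error"`
#' aborts on the first one.
#'
#' @param x Sequences: a named character vector, an unnamed character vector
#'   (ids are generated), a `Biostrings::AAStringSet`, or a data frame with
#'   columns `id` and `sequence`.
#' @param scheme An [raac_scheme].
#' @param nonstandard `"drop"` or `"error"`.
#' @return A tibble with columns `id`, `sequence` (the reduced string) and
#'   `dropped` (count of removed non-canonical residues).
#' @examples
#' sch <- raac_type33()[["2"]]
#' reduce_sequences(c(p1 = "CWC"), sch) # "CSC"
#' @export
reduce_sequences <- function(x, scheme, nonstandard = c("drop", "error")) {
  nonstandard <- match.arg(nonstandard)
  stopifnot(inherits(scheme, "raac_scheme"))
  x <- as_named_sequences(x)
  seqs <- toupper(unname(x))
  ids <- names(x)

  canon <- paste(AA_CANONICAL, collapse = "")
  noncanon_re <- paste0("[^", canon, "]")
  stripped <- gsub(noncanon_re, "", seqs)
  dropped <- nchar(seqs) - nchar(stripped)
  if (nonstandard == "error" && any(dropped > 0)) {
    i <- which(dropped > 0)[1]
    bad <- regmatches(seqs[i], regexpr(noncanon_re, seqs[i]))
    abort(
      paste0("Non-canonical residue '", bad, "' in sequence ", ids[i]),
      class = "raacpred_error_noncanonical"
    )
  }
  if (any(nchar(stripped) == 0)) {
    abort(
      paste0("Sequence(s) empty after dropping non-canonical residues: ",
             paste(ids[nchar(stripped) == 0], collapse = ", ")),
      class = "raacpred_error_empty_sequence"
    )
  }
  from <- paste(unlist(scheme$groups), collapse = "")
  to <- paste(rep(scheme$representatives, lengths(scheme$groups)),
              collapse = "")
  tibble::tibble(
    id = ids,
    sequence = chartr(from, to, stripped),
    dropped = as.integer(dropped)
  )
}

#' @rdname reduce_sequences
#' @param seq A single sequence string.
#' @return `reduce_sequence()` returns the reduced string with attribute
#'   `"dropped"`.
#' @export
reduce_sequence <- function(seq, scheme, nonstandard = c("drop", "error")) {
  out <- reduce_sequences(c(seq_1 = seq), scheme, nonstandard)
  structure(out$sequence, dropped = out$dropped)
}

# Coerce the accepted sequence inputs to a named character vector.
as_named_sequences <- function(x) {
  if (methods::is(x, "AAStringSet") || methods::is(x, "XStringSet")) {
    x <- setNames(as.character(x), names(x))
  } else if (is.data.frame(x)) {
    stopifnot(all(c("id", "sequence") %in% names(x)))
    x <- setNames(x$sequence, x$id)
  } else if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq_", seq_along(x))
  } else {
    abort("Unsupported sequence input type")
  }
  if (length(x) == 0) abort("No sequences supplied",
                            class = "raacpred_error_empty_input")
  x
}

#' Read a FASTA file as a named character vector of sequences
#'
#' Thin wrapper over `Biostrings::readAAStringSet()`; identifiers are
#' truncated at the first whitespace, matching common usage.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}
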