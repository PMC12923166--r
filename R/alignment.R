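#' Read a labeled multiple sequence alignment
#'
#' Imports an aligned FASTA file and splits its records into a target set
#' (the taxa the primers should amplify) and an exclusion set (typically
#' the host, whose amplification must be avoided). Residues are
#' uppercased, U is normalized to T and "." gaps to "-", and terminal
#' gap runs -- introduced by partial database records -- are masked so
#' they can be told apart from genuine internal indels.
#'
#' @param path Path to an aligned FASTA file (all records equal length).
#' @param targets Target-set designation: a single integer N ("the first
#'   N records are targets"), a character vector of record ids, or the
#'   path of a text file with one id per line.
#' @return An object of class `mbc_alignment`: a list with `ids`,
#'   residue matrix `mat` (records x columns), `set` (factor
#'   target/exclusion), terminal-gap mask vectors `mask_first`/`mask_last`
#'   (1-based; NA for all-gap records) and `n_columns`.
#' @export
read_alignment <- function(path, targets) {
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  recs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop("cannot parse FASTA: ", path, " (",
                                            conditionMessage(e), ")", call. = FALSE))
  if (length(recs) < 2) stop("alignment needs at least 2 records", call. = FALSE)
  ids <- sub("\\s.*$", "", names(recs))
  seqs <- normalize_residues(as.character(recs))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1) {
    stop("records have unequal aligned lengths (", paste(unique(widths), collapse = ", "),
         "); input must be a multiple sequence alignment", call. = FALSE)
  }
  target_ids <- resolve_targets(targets, ids)
  set <- factor(ifelse(ids %in% target_ids, "target", "exclusion"),
                levels = c("target", "exclusion"))
  n_t <- sum(set == "target"); n_e <- sum(set == "exclusion")
  if (n_t < 1 || n_e < 1) {
    stop("both a nonempty target and a nonempty exclusion set are required ",
         "(got ", n_t, " target, ", n_e, " exclusion)", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- ids
  aln <- structure(
    list(ids = ids, mat = mat, set = set, n_columns = unique(widths),
         mask_first = rep(NA_integer_, length(ids)),
         mask_last = rep(NA_integer_, length(ids))),
    class = "mbc_alignment")
  mask_terminal_gaps(aln)
}

resolve_targets <- function(targets, ids) {
  if (is.numeric(targets) && length(targets) == 1) {
    n <- as.integer(targets)
    if (n < 1 || n >= length(ids)) {
      stop("targets = ", n, " must leave a nonempty exclusion set among ",
           length(ids), " records", call. = FALSE)
    }
    return(ids[seq_len(n)])
  }
  if (is.character(targets)) {
    if (length(targets) == 1 && file.exists(targets)) {
      targets <- readLines(targets, warn = FALSE)
      targets <- targets[nzchar(trimws(targets))]
    }
    missing <- setdiff(targets, ids)
    if (length(missing)) {
      stop("target ids not present in the alignment: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    return(targets)
  }
  stop("targets must be an integer count, an id vector, or an id-list file",
       call. = FALSE)
}

#' Mask terminal gap runs
#'
#' Records each sequence's first and last non-gap column. Gap runs
#' outside this range stem from partial sequences and are excluded from
#' column statistics and window coverage; internal gaps remain genuine.
#' All-gap records get an empty mask and a warning.
#'
#' @param alignment An `mbc_alignment`.
#' @return The alignment with `mask_first`/`mask_last` set.
#' @export
mask_terminal_gaps <- function(alignment) {
  nongap <- alignment$mat != "-"
  for (i in seq_along(alignment$ids)) {
    w <- which(nongap[i, ])
    if (length(w) == 0) {
      warning("record '", alignment$ids[i], "' is all gaps; it is masked out",
              call. = FALSE)
      alignment$mask_first[i] <- NA_integer_
      alignment$mask_last[i] <- NA_integer_
    } else {
      alignment$mask_first[i] <- w[1]
      alignment$mask_last[i] <- w[length(w)]
    }
  }
  alignment
}

# records x columns logical: does record's terminal mask cover the column?
coverage_matrix <- function(alignment) {
  cols <- seq_len(alignment$n_columns)
  mf <- alignment$mask_first
  ml <- alignment$mask_last
  mf[is.na(mf)] <- alignment$n_columns + 1L   # all-gap: covers nothing
  ml[is.na(ml)] <- 0L
  outer(mf, cols, `<=`) & outer(ml, cols, `>=`)
}

#' Per-column gap/ambiguity fraction
#'
#' The fraction of covering records (terminal-gap regions excluded from
#' numerator and denominator) that carry an internal gap or a non-ACGT
#' character in the column. Columns covered by no record return 1 so
#' they are always trimmed.
#'
#' @param alignment An `mbc_alignment` with terminal masks computed.
#' @param columns Column indices (default: all).
#' @return Numeric vector of fractions in \[0, 1\].
#' @export
column_badness <- function(alignment, columns = seq_len(alignment$n_columns)) {
  cov <- coverage_matrix(alignment)[, columns, drop = FALSE]
  bad <- (alignment$mat == "-" | !(alignment$mat %in% c("A", "C", "G", "T")))
  bad <- bad[, columns, drop = FALSE]
  n_cov <- colSums(cov)
  frac <- colSums(bad & cov) / n_cov
  frac[n_cov == 0] <- 1
  unname(frac)
}

#' Trim high-gap/ambiguous columns
#'
#' Removes columns whose internal-gap plus ambiguity fraction exceeds
#' `max_frac` (strictly greater; a column at exactly the threshold is
#' kept). The original column indices of the kept columns are retained
#' so reported sites can be located in the user's input alignment.
#'
#' @param alignment An `mbc_alignment`.
#' @param max_frac Badness threshold, default 0.20.
#' @return An `mbc_trimmed_alignment`: the trimmed alignment plus
#'   `kept_columns` (1-based original indices) and `max_frac`.
#' @export
trim_columns <- function(alignment, max_frac = 0.20) {
  stopifnot(max_frac >= 0, max_frac <= 1)
  badness <- column_badness(alignment)
  keep <- which(badness <= max_frac)
  if (length(keep) == 0) {
    stop("alignment too gappy: every column exceeds the ", max_frac,
         " gap/ambiguity threshold", call. = FALSE)
  }
  kept0 <- if (inherits(alignment, "mbc_trimmed_alignment"))
    alignment$kept_columns else seq_len(alignment$n_columns)
  out <- alignment
  out$mat <- alignment$mat[, keep, drop = FALSE]
  out$n_columns <- length(keep)
  out$kept_columns <- kept0[keep]
  out$max_frac <- max_frac
  class(out) <- unique(c("mbc_trimmed_alignment", class(alignment)))
  mask_terminal_gaps(out)
}

#' Map a trimmed column back to the original alignment
#'
#' @param trimmed An `mbc_trimmed_alignment`.
#' @param pos 1-based column index in the trimmed alignment (vectorized).
#' @return 1-based column index in the original alignment.
#' @export
to_original_position <- function(trimmed, pos) {
  stopifnot(inherits(trimmed, "mbc_trimmed_alignment"))
  if (any(pos < 1 | pos > trimmed$n_columns)) {
    stop("position out of range 1..", trimmed$n_columns, call. = FALSE)
  }
  trimmed$kept_columns[pos]
}

#' Write an alignment to FASTA (plus a column map for trimmed input)
#'
#' @param alignment An `mbc_alignment` or `mbc_trimmed_alignment`.
#' @param path Output FASTA path.
#' @param map_path Optional path for a two-column TSV mapping trimmed to
#'   original 1-based columns (trimmed alignments only).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path, map_path = NULL) {
  seqs <- apply(alignment$mat, 1, paste, collapse = "")
  xs <- Biostrings::BStringSet(seqs)
  names(xs) <- alignment$ids
  Biostrings::writeXStringSet(xs, path)
  if (!is.null(map_path)) {
    stopifnot(inherits(alignment, "mbc_trimmed_alignment"))
    utils::write.table(
      data.frame(trimmed = seq_len(alignment$n_columns),
                 original = alignment$kept_columns),
      map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @export
print.mbc_alignment <- function(x, ...) {
  cat("<mbc_alignment> ", length(x$ids), " records x ", x$n_columns, " columns (",
      sum(x$set == "target"), " target / ", sum(x$set == "exclusion"),
      " exclusion)\n", sep = "")
  if (inherits(x, "mbc_trimmed_alignment")) {
    cat("  trimmed from ", max(x$kept_columns), " original columns (max_frac = ",
        x$max_frac, ")\n", sep = "")
  }
  invisible(x)
}
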