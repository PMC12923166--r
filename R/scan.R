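#' Scan configuration
#'
#' Defaults follow the published tool settings: a 20 bp window, score
#' mismatch threshold mm = 2, minimum reported score 0.5, and no gaps or
#' ambiguous bases allowed in a candidate.
#'
#' @param window_length Sliding-window size in bp (intended primer
#'   length), default 20, minimum 10.
#' @param mm Mismatch threshold of the discriminative score (depth of
#'   cumulative profile averaging), 1..4, default 2.
#' @param min_score Minimum score kept by [filter_candidates()]
#'   (inclusive), default 0.5.
#' @param max_gaps Maximum gap characters tolerated inside a candidate
#'   window, default 0.
#' @param max_ambiguous Maximum non-ACGT characters tolerated in a
#'   candidate, default 0.
#' @return A `scan_config` list.
#' @export
scan_config <- function(window_length = 20, mm = 2, min_score = 0.5,
                        max_gaps = 0, max_ambiguous = 0) {
  stopifnot(window_length >= 10, mm >= 1, mm <= 4,
            min_score >= -1, min_score <= 1, max_gaps >= 0, max_ambiguous >= 0)
  structure(list(window_length = as.integer(window_length), mm = as.integer(mm),
                 min_score = min_score, max_gaps = as.integer(max_gaps),
                 max_ambiguous = as.integer(max_ambiguous)),
            class = "scan_config")
}

#' Count sequence variants in one window
#'
#' Extracts the window from every record whose terminal mask fully
#' covers it, drops gap characters, and counts identical degapped
#' strings separately for the target and exclusion sets. Variants are
#' kept in order of first occurrence so downstream tie-breaking is
#' deterministic.
#'
#' @param trimmed An `mbc_trimmed_alignment` (or plain `mbc_alignment`).
#' @param start 1-based first window column.
#' @param length Window length in columns.
#' @return A `window_variants` list: `start`, `length`, per-set named
#'   abundance vectors `variants$target` / `variants$exclusion`, and
#'   per-set `covered` counts.
#' @export
extract_window_variants <- function(trimmed, start, length) {
  end <- start + length - 1L
  stopifnot(start >= 1, end <= trimmed$n_columns)
  covered <- !is.na(trimmed$mask_first) &
    trimmed$mask_first <= start & trimmed$mask_last >= end
  variants <- list()
  for (lab in c("target", "exclusion")) {
    rows <- which(covered & trimmed$set == lab)
    if (length(rows) == 0) {
      variants[[lab]] <- stats::setNames(integer(0), character(0))
      next
    }
    win <- apply(trimmed$mat[rows, start:end, drop = FALSE], 1, paste, collapse = "")
    deg <- gsub("-", "", win, fixed = TRUE)
    lev <- unique(deg)                       # first-occurrence order
    counts <- table(factor(deg, levels = lev))
    variants[[lab]] <- stats::setNames(as.integer(counts), lev)
  }
  structure(list(start = start, length = length, variants = variants,
                 covered = c(target = sum(covered & trimmed$set == "target"),
                             exclusion = sum(covered & trimmed$set == "exclusion"))),
            class = "window_variants")
}

#' Pick the primer candidate for a window
#'
#' The most abundant degapped target-set variant; ties go to the variant
#' first seen in record order, so results are reproducible.
#'
#' @param wv A `window_variants` object.
#' @return The candidate string, or NULL if no target record covers the
#'   window.
#' @export
select_candidate_variant <- function(wv) {
  v <- wv$variants$target
  if (length(v) == 0) return(NULL)
  names(v)[which.max(v)]   # which.max takes the first maximum
}

#' Edit distance between a candidate and a variant
#'
#' Levenshtein distance (substitutions, insertions and deletions each
#' cost 1) on degapped strings; symmetric. Vectorized over `variant`.
#'
#' @param candidate Candidate primer string.
#' @param variant One or more variant strings.
#' @return Integer vector of distances.
#' @export
count_mismatches <- function(candidate, variant) {
  stopifnot(nzchar(candidate))
  drop(utils::adist(candidate, variant))
}

#' Mismatch profile of a sequence set against a candidate
#'
#' The abundance-weighted distribution of a set's covered records over
#' edit distance to the candidate, binned at exactly 0, 1, 2, 3 and
#' 4-or-more mismatches. Fractions sum to 1.
#'
#' @param wv A `window_variants` object.
#' @param candidate Candidate primer string.
#' @param set `"target"` or `"exclusion"`.
#' @return Numeric vector of length 5 (bins 0,1,2,3,>=4).
#' @export
build_mismatch_profile <- function(wv, candidate, set = c("target", "exclusion")) {
  set <- match.arg(set)
  v <- wv$variants[[set]]
  n <- wv$covered[[set]]
  if (n < 1) stop("no covered ", set, " records in window at ", wv$start, call. = FALSE)
  d <- pmin(count_mismatches(candidate, names(v)), 4L)
  f <- vapply(0:4, function(k) sum(v[d == k]) / n, numeric(1))
  stats::setNames(f, c("mm0", "mm1", "mm2", "mm3", "mm4plus"))
}

#' Discriminative score of a target/exclusion profile pair
#'
#' Integrates the two mismatch profiles into one score: the average,
#' over cumulative mismatch depths k = 1..mm, of the difference between
#' the target and exclusion cumulative fractions at up to k-1
#' mismatches,
#' \deqn{score = \frac{1}{mm}\sum_{k=1}^{mm}\Big(\sum_{i=1}^{k} t_i - \sum_{i=1}^{k} e_i\Big)}
#' with \eqn{t_i}/\eqn{e_i} the fraction of the target/exclusion set at
#' exactly i-1 mismatches. A score of 1 captures 100% of the target
#' perfectly while excluding 100% of non-targets at the given threshold;
#' identical profiles score 0; values are in \[-1, 1\] and reported
#' unclamped.
#'
#' @param target,exclude Length-5 mismatch profiles (bins 0..3, >=4).
#' @param mm Mismatch threshold, 1..4 (default 2).
#' @return The score (numeric scalar).
#' @export
#' @examples
#' discriminative_score(c(1, 0, 0, 0, 0), c(0, 0, 0, 0, 1), mm = 2)  # 1
discriminative_score <- function(target, exclude, mm = 2) {
  if (!(length(target) == 5 && length(exclude) == 5)) {
    stop("profiles must have 5 bins (0,1,2,3,>=4 mismatches)", call. = FALSE)
  }
  if (mm < 1 || mm > 4) stop("mm must be in 1..4", call. = FALSE)
  ct <- cumsum(target)
  ce <- cumsum(exclude)
  mean(ct[seq_len(mm)] - ce[seq_len(mm)])
}

#' Scan an alignment for discriminative primer-binding sites
#'
#' Slides a primer-length window over every start position, selects the
#' most abundant target variant as candidate, builds both mismatch
#' profiles and computes the discriminative score. Windows without
#' covered target or exclusion records are skipped. Output is
#' unfiltered; apply [filter_candidates()] and [group_overlapping()]
#' before reporting.
#'
#' @param trimmed An `mbc_trimmed_alignment` (use [trim_columns()]
#'   first) or plain `mbc_alignment`.
#' @param config A [scan_config()].
#' @return A data.frame of class `mbc_sites`, one row per evaluable
#'   window: name, start/end (1-based inclusive, trimmed coordinates),
#'   orig_start/orig_end (input-alignment coordinates), length, score,
#'   tgt_mm0..tgt_mm4plus and exc_mm0..exc_mm4plus profile fractions,
#'   gaps/ambiguous counts of the candidate, group (NA until grouped)
#'   and sequence. Per-stage counts are attached as attributes.
#' @export
scan_alignment <- function(trimmed, config = scan_config()) {
  L <- config$window_length
  if (trimmed$n_columns < L) {
    stop("alignment (", trimmed$n_columns, " columns) is shorter than the window (",
         L, " bp)", call. = FALSE)
  }
  kept <- if (inherits(trimmed, "mbc_trimmed_alignment"))
    trimmed$kept_columns else seq_len(trimmed$n_columns)
  starts <- seq_len(trimmed$n_columns - L + 1L)

  # precompute per-record coverage bounds once; string rows for fast substr
  rowstr <- apply(trimmed$mat, 1, paste, collapse = "")
  mf <- trimmed$mask_first
  ml <- trimmed$mask_last
  is_t <- trimmed$set == "target"

  rows <- vector("list", length(starts))
  n_skipped <- 0L
  for (s in starts) {
    e <- s + L - 1L
    covered <- !is.na(mf) & mf <= s & ml >= e
    ct <- covered & is_t
    ce <- covered & !is_t
    if (!any(ct) || !any(ce)) { n_skipped <- n_skipped + 1L; next }
    deg_t <- gsub("-", "", substr(rowstr[ct], s, e), fixed = TRUE)
    deg_e <- gsub("-", "", substr(rowstr[ce], s, e), fixed = TRUE)
    lev_t <- unique(deg_t)
    cnt_t <- as.integer(table(factor(deg_t, levels = lev_t)))
    cand <- lev_t[which.max(cnt_t)]
    if (!nzchar(cand)) { n_skipped <- n_skipped + 1L; next }  # all-gap window
    dt <- pmin(count_mismatches(cand, lev_t), 4L)
    tf <- vapply(0:4, function(k) sum(cnt_t[dt == k]), numeric(1)) / sum(ct)
    lev_e <- unique(deg_e)
    cnt_e <- as.integer(table(factor(deg_e, levels = lev_e)))
    de <- pmin(count_mismatches(cand, lev_e), 4L)
    ef <- vapply(0:4, function(k) sum(cnt_e[de == k]), numeric(1)) / sum(ce)
    chars <- strsplit(cand, "", fixed = TRUE)[[1]]
    rows[[s]] <- data.frame(
      name = paste0("mbc-", s),
      start = s, end = e,
      orig_start = kept[s], orig_end = kept[e],
      length = nchar(cand),
      score = discriminative_score(tf, ef, config$mm),
      tgt_mm0 = tf[1], tgt_mm1 = tf[2], tgt_mm2 = tf[3], tgt_mm3 = tf[4],
      tgt_mm4plus = tf[5],
      exc_mm0 = ef[1], exc_mm1 = ef[2], exc_mm2 = ef[3], exc_mm3 = ef[4],
      exc_mm4plus = ef[5],
      gaps = L - nchar(cand),
      ambiguous = sum(!(chars %in% c("A", "C", "G", "T"))),
      group = NA_integer_,
      sequence = cand,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(name = character(0), start = integer(0), end = integer(0),
                      orig_start = integer(0), orig_end = integer(0),
                      length = integer(0), score = numeric(0),
                      tgt_mm0 = numeric(0), tgt_mm1 = numeric(0),
                      tgt_mm2 = numeric(0), tgt_mm3 = numeric(0),
                      tgt_mm4plus = numeric(0),
                      exc_mm0 = numeric(0), exc_mm1 = numeric(0),
                      exc_mm2 = numeric(0), exc_mm3 = numeric(0),
                      exc_mm4plus = numeric(0),
                      gaps = integer(0), ambiguous = integer(0),
                      group = integer(0), sequence = character(0))
  }
  rownames(out) <- NULL
  structure(out, class = c("mbc_sites", "data.frame"), config = config,
            n_windows = length(starts), n_skipped = n_skipped)
}

#' Filter candidate sites
#'
#' Keeps sites with score at or above `min_score` (inclusive) and with a
#' candidate carrying at most `max_gaps` gap and `max_ambiguous`
#' non-ACGT characters; order is preserved. An empty result is valid.
#'
#' @param sites An `mbc_sites` data.frame.
#' @param config A [scan_config()].
#' @return The filtered `mbc_sites`.
#' @export
filter_candidates <- function(sites, config = attr(sites, "config")) {
  if (is.null(config)) config <- scan_config()
  keep <- sites$score >= config$min_score &
    sites$gaps <= config$max_gaps &
    sites$ambiguous <= config$max_ambiguous
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(sites), config = config,
            n_windows = attr(sites, "n_windows"),
            n_skipped = attr(sites, "n_skipped"),
            n_filtered = sum(!keep))
}

#' Group overlapping candidate sites
#'
#' Connected components of window overlap (sharing at least one trimmed
#' column) receive the same group id; ids run consecutively from 1 in
#' positional order. Abutting windows do not overlap.
#'
#' @param sites An `mbc_sites` data.frame sorted by start.
#' @return The sites with `group` assigned.
#' @export
group_overlapping <- function(sites) {
  if (nrow(sites) == 0) return(sites)
  o <- order(sites$start, sites$end)
  sites <- sites[o, , drop = FALSE]
  g <- integer(nrow(sites))
  g[1] <- 1L
  max_end <- sites$end[1]
  for (i in seq_len(nrow(sites))[-1]) {
    if (sites$start[i] > max_end) g[i] <- g[i - 1] + 1L else g[i] <- g[i - 1]
    max_end <- max(max_end, sites$end[i])
  }
  sites$group <- g
  rownames(sites) <- NULL
  sites
}

#' Write the candidate-site report
#'
#' Tab-separated table with one row per site: positional information in
#' both trimmed and original 1-based coordinates, the score (4
#' decimals), both mismatch profiles as percentages (1 decimal), the
#' overlap group and the candidate sequence. Byte-identical across
#' reruns on identical input.
#'
#' @param sites A filtered, grouped `mbc_sites`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(sites, path) {
  pct <- function(x) sprintf("%.1f", 100 * x)
  df <- data.frame(
    name = sites$name,
    start = sites$start, end = sites$end,
    orig_start = sites$orig_start, orig_end = sites$orig_end,
    length = sites$length,
    score = sprintf("%.4f", sites$score),
    tgt_mm0 = pct(sites$tgt_mm0), tgt_mm1 = pct(sites$tgt_mm1),
    tgt_mm2 = pct(sites$tgt_mm2), tgt_mm3 = pct(sites$tgt_mm3),
    tgt_mm4plus = pct(sites$tgt_mm4plus),
    exc_mm0 = pct(sites$exc_mm0), exc_mm1 = pct(sites$exc_mm1),
    exc_mm2 = pct(sites$exc_mm2), exc_mm3 = pct(sites$exc_mm3),
    exc_mm4plus = pct(sites$exc_mm4plus),
    group = sites$group,
    sequence = sites$sequence,
    stringsAsFactors = FALSE)
  con <- file(path, open = "wb")   # fixed EOL across platforms
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df)) {
    writeLines(do.call(paste, c(unname(df), sep = "\t")), con)
  }
  invisible(path)
}

#' Read back a candidate-site report
#'
#' @param path A TSV written by [write_report()].
#' @return A data.frame with scores numeric and profiles as fractions.
#' @export
read_report <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in grep("^(tgt|exc)_mm", colnames(df), value = TRUE)) {
    df[[col]] <- df[[col]] / 100
  }
  df
}

#' @export
print.mbc_sites <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("<mbc_sites> ", nrow(x), " candidate site(s)", sep = "")
  if (!is.null(cfg)) {
    cat(" (window ", cfg$window_length, " bp, mm = ", cfg$mm,
        ", min score ", cfg$min_score, ")", sep = "")
  }
  cat("\n")
  if (nrow(x)) {
    show <- intersect(c("name", "start", "end", "orig_start", "orig_end",
                        "score", "group", "sequence"), colnames(x))
    print(utils::head(as.data.frame(x)[, show, drop = FALSE], 10))
    if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more\n")
  }
  invisible(x)
}

#' @export
summary.mbc_sites <- function(object, ...) {
  cat("Candidate discriminative primer sites\n")
  cat("  windows scanned: ", attr(object, "n_windows") %||% NA,
      "; skipped: ", attr(object, "n_skipped") %||% NA, "\n", sep = "")
  cat("  sites: ", nrow(object), "; groups: ",
      length(unique(stats::na.omit(object$group))), "\n", sep = "")
  if (nrow(object)) {
    cat("  score range: ", sprintf("%.4f", min(object$score)), " .. ",
        sprintf("%.4f", max(object$score)), "\n", sep = "")
  }
  invisible(object)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
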