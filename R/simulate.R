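#' Describe a planted discriminative site
#'
#' Specifies one window to plant in a synthetic alignment: where it
#' starts, and the exact mismatch-count composition of the target and
#' exclusion sets relative to the window's candidate sequence. Fraction
#' names are mismatch counts; "4" means four-or-more (planted as 6
#' substitutions).
#'
#' @param start 1-based first column of the window.
#' @param length Window length in bp (default 20).
#' @param target_fractions Named numeric, e.g. `c("0" = 0.9, "1" = 0.1)`;
#'   must sum to 1.
#' @param exclusion_fractions Same shape for the exclusion set (default
#'   `c("4" = 1)`: every exclusion record at >= 4 mismatches).
#' @return A `planted_site` list.
#' @export
planted_site <- function(start, length = 20,
                         target_fractions = c("0" = 1),
                         exclusion_fractions = c("4" = 1)) {
  chk <- function(f, who) {
    if (abs(sum(f) - 1) > 1e-9) stop(who, " fractions must sum to 1", call. = FALSE)
    if (is.null(names(f)) || !all(names(f) %in% as.character(0:4))) {
      stop(who, " fractions must be named with mismatch counts 0..4", call. = FALSE)
    }
    if (any(as.integer(names(f)) > length)) {
      stop(who, " mismatch counts exceed the site length", call. = FALSE)
    }
  }
  chk(target_fractions, "target"); chk(exclusion_fractions, "exclusion")
  structure(list(start = as.integer(start), length = as.integer(length),
                 target_fractions = target_fractions,
                 exclusion_fractions = exclusion_fractions),
            class = "planted_site")
}

# 5-bin profile from named fractions (bin 5 = >=4)
fractions_to_profile <- function(f) {
  p <- stats::setNames(numeric(5), c("mm0", "mm1", "mm2", "mm3", "mm4plus"))
  for (nm in names(f)) p[as.integer(nm) + 1] <- p[as.integer(nm) + 1] + f[[nm]]
  p
}

# integer apportionment of n by fractions (largest remainder, deterministic)
apportion <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# mutate `m` positions of `window` (chars) so that edit distance is exactly m
# (or >= 4 when m codes the open bin); resamples on accidental collapse
mutate_window <- function(window, m, at_least4 = FALSE) {
  n_sub <- if (at_least4) min(length(window), 6L) else m
  target_check <- function(d) if (at_least4) d >= 4 else d == m
  cand <- paste(window, collapse = "")
  for (try in 1:200) {
    out <- window
    pos <- sample.int(length(window), n_sub)
    for (p in pos) {
      out[p] <- sample(setdiff(c("A", "C", "G", "T"), window[p]), 1)
    }
    d <- drop(utils::adist(cand, paste(out, collapse = "")))
    if (target_check(d)) return(out)
  }
  stop("could not plant a window at the prescribed edit distance ", m,
       call. = FALSE)
}

#' Generate a synthetic alignment with planted discriminative sites
#'
#' Builds a gap-augmented alignment whose background columns are drawn
#' from one consensus with identical noise in both sets (so background
#' windows are non-discriminative), and whose planted windows carry the
#' exact prescribed mismatch-count composition relative to a candidate
#' sequence. Random internal gaps are placed outside the planted
#' windows, and a fraction of records is truncated at the ends (without
#' reaching any planted window) to create realistic terminal gaps.
#' Defaults mirror the published use case: 118 target (fungal) versus
#' 46 exclusion (host-order) records.
#'
#' @param n_target,n_exclusion Set sizes (defaults 118 and 46).
#' @param n_columns Alignment width before gap columns (default 600).
#' @param sites List of [planted_site()] specs (default one perfect
#'   site at column 201).
#' @param gap_rate Per-position internal gap probability outside planted
#'   windows (default 0.01).
#' @param truncation_rate Fraction of records with a terminal
#'   truncation (default 0.1).
#' @param background_identity Per-position probability that a
#'   background base matches the consensus (default 0.98).
#' @param mm Mismatch threshold used for the expected score in the
#'   truth record (default 2).
#' @param seed Integer seed; same seed, same output, byte for byte.
#' @return List with `alignment` (an `mbc_alignment`) and `truth` (per
#'   site: location, candidate, expected profiles and expected score).
#' @export
generate_planted_alignment <- function(n_target = 118, n_exclusion = 46,
                                       n_columns = 600,
                                       sites = list(planted_site(201)),
                                       gap_rate = 0.01, truncation_rate = 0.1,
                                       background_identity = 0.98,
                                       mm = 2, seed = 1) {
  stopifnot(n_target >= 1, n_exclusion >= 1)
  for (s in sites) {
    if (s$start + s$length - 1 > n_columns) stop("site does not fit", call. = FALSE)
  }
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  n <- n_target + n_exclusion
  consensus <- sample(bases, n_columns, replace = TRUE)
  site_cols <- unlist(lapply(sites, function(s) s$start:(s$start + s$length - 1)))
  if (anyDuplicated(site_cols)) stop("planted sites overlap", call. = FALSE)
  bg_cols <- setdiff(seq_len(n_columns), site_cols)

  mat <- matrix(rep(consensus, each = n), nrow = n)
  # background noise, identical process in both sets
  for (j in bg_cols) {
    flip <- stats::runif(n) > background_identity
    if (any(flip)) {
      mat[flip, j] <- vapply(mat[flip, j],
                             function(b) sample(setdiff(bases, b), 1), "")
    }
  }

  set <- factor(rep(c("target", "exclusion"), c(n_target, n_exclusion)),
                levels = c("target", "exclusion"))
  truth <- vector("list", length(sites))
  for (si in seq_along(sites)) {
    s <- sites[[si]]
    cols <- s$start:(s$start + s$length - 1)
    cand <- consensus[cols]
    for (lab in c("target", "exclusion")) {
      fr <- if (lab == "target") s$target_fractions else s$exclusion_fractions
      rows <- which(set == lab)
      counts <- apportion(fr, length(rows))
      if (!isTRUE(all.equal(counts / length(rows), unname(fr), tolerance = 1e-9))) {
        warning("site ", si, " ", lab,
                " fractions are not exactly representable with ", length(rows),
                " records; planted profile rounded", call. = FALSE)
      }
      idx <- 1
      for (bi in seq_along(fr)) {
        m <- as.integer(names(fr)[bi])
        for (r in seq_len(counts[bi])) {
          row <- rows[idx]; idx <- idx + 1
          mat[row, cols] <- if (m == 0) cand else
            mutate_window(cand, m, at_least4 = (m == 4))
        }
      }
    }
    tp <- fractions_to_profile(s$target_fractions)
    ep <- fractions_to_profile(s$exclusion_fractions)
    truth[[si]] <- list(start = s$start, length = s$length,
                        candidate = paste(cand, collapse = ""),
                        expected_target_profile = tp,
                        expected_exclusion_profile = ep,
                        expected_score = discriminative_score(tp, ep, mm = mm),
                        mm = mm, seed = seed)
  }

  # internal gaps outside planted windows
  if (gap_rate > 0 && length(bg_cols)) {
    gap_mask <- matrix(stats::runif(n * length(bg_cols)) < gap_rate,
                       nrow = n)
    mat[, bg_cols][gap_mask] <- "-"
  }
  # terminal truncations, never reaching a planted window
  first_site <- if (length(sites)) min(vapply(sites, `[[`, 1L, "start")) else n_columns
  last_site <- if (length(sites))
    max(vapply(sites, function(s) s$start + s$length - 1L, 1L)) else 1L
  head_room <- max(first_site - 1L, 0L)
  tail_room <- max(n_columns - last_site, 0L)
  for (i in seq_len(n)) {
    if (stats::runif(1) < truncation_rate) {
      if (stats::runif(1) < 0.5 && head_room > 0) {
        cut <- sample.int(head_room, 1)
        mat[i, seq_len(cut)] <- "-"
      } else if (tail_room > 0) {
        cut <- sample.int(tail_room, 1)
        mat[i, (n_columns - cut + 1):n_columns] <- "-"
      }
    }
  }

  ids <- sprintf("%s_%03d", ifelse(set == "target", "tgt", "exc"),
                 stats::ave(seq_len(n), set, FUN = seq_along))
  rownames(mat) <- ids
  aln <- structure(list(ids = ids, mat = mat, set = set, n_columns = n_columns,
                        mask_first = rep(NA_integer_, n),
                        mask_last = rep(NA_integer_, n)),
                   class = "mbc_alignment")
  list(alignment = mask_terminal_gaps(aln), truth = truth)
}

#' Generate a reference set with known mismatch loads
#'
#' Embeds the primer, mutated at exactly the prescribed number of
#' positions, inside random flanking sequence — one reference per entry
#' of `mismatch_counts`. Mutations at degenerate primer positions are
#' drawn outside the position's IUPAC set, so the planted Hamming
#' distance is exact. Every second reference is reverse-complemented so
#' strand handling is exercised.
#'
#' @param primer IUPAC primer string.
#' @param mismatch_counts Integer vector; one reference is generated per
#'   element with exactly that many planted mismatches.
#' @param flank_length Random flank on each side (default 30).
#' @param seed Integer seed.
#' @return Named character vector of reference sequences.
#' @export
generate_reference_set <- function(primer, mismatch_counts, flank_length = 30,
                                   seed = 1) {
  primer <- normalize_residues(primer)
  sets <- lapply(seq_chars(primer), iupac_set)
  stopifnot(all(mismatch_counts <= length(sets)))
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  out <- character(length(mismatch_counts))
  for (i in seq_along(mismatch_counts)) {
    core <- vapply(sets, function(s) sample(s, 1)[[1]], "")
    m <- mismatch_counts[i]
    if (m > 0) {
      pos <- sample.int(length(core), m)
      for (p in pos) {
        choices <- setdiff(bases, sets[[p]])
        if (length(choices) == 0) stop("position ", p, " is N; cannot mismatch",
                                       call. = FALSE)
        core[p] <- sample(choices, 1)[[1]]
      }
    }
    ref <- paste0(paste(sample(bases, flank_length, replace = TRUE), collapse = ""),
                  paste(core, collapse = ""),
                  paste(sample(bases, flank_length, replace = TRUE), collapse = ""))
    if (i %% 2 == 0) ref <- reverse_complement(ref)
    out[i] <- ref
  }
  names(out) <- sprintf("ref_%03d_mm%d", seq_along(out), mismatch_counts)
  out
}
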