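#' GC content of a (possibly degenerate) primer
#'
#' Each position contributes the fraction of its IUPAC set that is G or
#' C: S counts 1, Y or N count 0.5, A counts 0. Equals the mean GC of
#' all degenerate expansions.
#'
#' @param sequence IUPAC nucleotide string.
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' gc_content("AYGT")  # 0.375
gc_content <- function(sequence) {
  chars <- seq_chars(normalize_residues(sequence))
  w <- vapply(chars, function(ch) {
    s <- iupac_set(ch)
    sum(s %in% c("G", "C")) / length(s)
  }, numeric(1))
  mean(w)
}

# Nearest-neighbor stack parameters, unified oligonucleotide set
# (Allawi & SantaLucia 1997): dH kcal/mol, dS cal/(mol K), 5'->3' top strand.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

nn_tm_plain <- function(sequence, Na, dnac1, dnac2) {
  chars <- seq_chars(sequence)
  n <- length(chars)
  dh <- 0; ds <- 0
  for (term in chars[c(1, n)]) {        # terminal initiation penalties
    if (term %in% c("A", "T")) { dh <- dh + 2.3; ds <- ds + 4.1 }
    else                       { dh <- dh + 0.1; ds <- ds - 2.8 }
  }
  stacks <- paste0(chars[-n], chars[-1])
  dh <- dh + sum(NN_DH[stacks])
  ds <- ds + sum(NN_DS[stacks])
  ds <- ds + 0.368 * (n - 1) * log(Na * 1e-3)   # monovalent-salt entropy term
  k <- (dnac1 - dnac2 / 2) * 1e-9               # non-self-complementary duplex
  1000 * dh / (ds + 1.987 * log(k)) - 273.15
}

#' Primer melting temperature
#'
#' `wallace`: the 2(A+T) + 4(G+C) rule for quick screens. `nn` (default):
#' nearest-neighbor thermodynamics with the unified Allawi–SantaLucia
#' parameter set, entropy salt correction 0.368(N-1)ln\[Na+\], and
#' non-self-complementary duplex concentration (dnac1 - dnac2/2).
#' Degenerate primers are averaged over their expansions while
#' degeneracy is at most 64; beyond that the expectation of dH and dS
#' over the per-position base distributions is used.
#'
#' @param sequence IUPAC nucleotide string.
#' @param method `"nn"` or `"wallace"`.
#' @param Na Monovalent cation concentration in mM (default 50).
#' @param dnac1,dnac2 Strand concentrations in nM (default 25 each).
#' @return Temperature in degrees Celsius.
#' @export
#' @examples
#' melting_temperature("AAAA", method = "wallace")  # 8
melting_temperature <- function(sequence, method = c("nn", "wallace"),
                                Na = 50, dnac1 = 25, dnac2 = 25) {
  method <- match.arg(method)
  sequence <- normalize_residues(sequence)
  n <- nchar(sequence)
  if (n < 8) warning("sequence shorter than 8 bp; Tm estimate is unreliable",
                     call. = FALSE)
  if (method == "wallace") {
    # expected GC over ambiguity sets: 2N + 2*GC
    return(2 * n + 2 * gc_content(sequence) * n)
  }
  d <- degeneracy(sequence)
  if (d == 1) return(nn_tm_plain(sequence, Na, dnac1, dnac2))
  if (d <= 64) {
    return(mean(vapply(expand_degenerate(sequence),
                       nn_tm_plain, numeric(1), Na = Na, dnac1 = dnac1,
                       dnac2 = dnac2)))
  }
  nn_tm_expected(sequence, Na, dnac1, dnac2)
}

# expectation of dH/dS over independent per-position base distributions
nn_tm_expected <- function(sequence, Na, dnac1, dnac2) {
  sets <- lapply(seq_chars(sequence), iupac_set)
  n <- length(sets)
  dh <- 0; ds <- 0
  for (idx in c(1, n)) {
    p_at <- mean(sets[[idx]] %in% c("A", "T"))
    dh <- dh + p_at * 2.3 + (1 - p_at) * 0.1
    ds <- ds + p_at * 4.1 + (1 - p_at) * -2.8
  }
  for (i in seq_len(n - 1)) {
    pairs <- expand.grid(a = sets[[i]], b = sets[[i + 1]],
                         stringsAsFactors = FALSE)
    st <- paste0(pairs$a, pairs$b)
    dh <- dh + mean(NN_DH[st])
    ds <- ds + mean(NN_DS[st])
  }
  ds <- ds + 0.368 * (n - 1) * log(Na * 1e-3)
  k <- (dnac1 - dnac2 / 2) * 1e-9
  1000 * dh / (ds + 1.987 * log(k)) - 273.15
}

#' Construct a primer record
#'
#' Bundles an oriented primer with its physical properties. For a
#' reverse primer the sequence stored is the primer strand (5'->3'),
#' i.e. the reverse complement of the alignment-strand site it was
#' derived from.
#'
#' @param name Primer name.
#' @param sequence IUPAC string, 5'->3' on the primer strand.
#' @param orientation `"forward"` or `"reverse"`.
#' @param source_site Optional row of an `mbc_sites` report this primer
#'   was derived from.
#' @param tm_method Passed to [melting_temperature()].
#' @return A `primer_record` list with `gc_fraction`, `tm_celsius` and
#'   `degeneracy` filled in.
#' @export
primer_record <- function(name, sequence, orientation = c("forward", "reverse"),
                          source_site = NULL, tm_method = "nn") {
  orientation <- match.arg(orientation)
  sequence <- normalize_residues(sequence)
  structure(list(name = name, sequence = sequence, orientation = orientation,
                 source_site = source_site,
                 gc_fraction = gc_content(sequence),
                 tm_celsius = melting_temperature(sequence, method = tm_method),
                 degeneracy = degeneracy(sequence)),
            class = "primer_record")
}

#' @export
print.primer_record <- function(x, ...) {
  cat("<primer_record> ", x$name, " (", x$orientation, ") ", x$sequence, "\n",
      "  length ", nchar(x$sequence), " bp, GC ",
      sprintf("%.1f%%", 100 * x$gc_fraction), ", Tm ",
      sprintf("%.1f", x$tm_celsius), " C, degeneracy ", x$degeneracy, "\n",
      sep = "")
  invisible(x)
}

#' Propose a degenerate consensus primer for a window
#'
#' Starting from the most abundant target variant, greedily adds to
#' single positions the base that raises exact-match target coverage
#' the most per unit of added degeneracy, until the coverage goal is
#' reached or the degeneracy cap would be exceeded. Ties break to the
#' leftmost position, then the alphabetically first base, so the result
#' is deterministic. Positions where all target variants agree are never
#' altered, and coverage never decreases.
#'
#' @param wv A [extract_window_variants()] result.
#' @param coverage_goal Target fraction of covered target records that
#'   must match the primer exactly (default 1).
#' @param cap Maximum degeneracy (default 64).
#' @param name Name for the resulting record.
#' @return A `primer_record` with attributes `coverage` (achieved
#'   exact-match fraction) and `goal_met`.
#' @export
propose_degenerate_consensus <- function(wv, coverage_goal = 1, cap = 64,
                                         name = paste0("mbc-", wv$start)) {
  v <- wv$variants$target
  if (length(v) == 0) stop("window has no covered target variants", call. = FALSE)
  cand <- select_candidate_variant(wv)
  total <- sum(v)
  same_len <- nchar(names(v)) == nchar(cand)
  vm <- lapply(strsplit(names(v)[same_len], "", fixed = TRUE), identity)
  vw <- unname(v[same_len])
  sets <- lapply(seq_chars(cand), iupac_set)

  matched <- function(sets) {
    vapply(vm, function(ch) all(mapply(function(c, s) c %in% s, ch, sets)),
           logical(1))
  }
  cov <- function(sets) sum(vw[matched(sets)]) / total
  deg <- function(sets) prod(lengths(sets))

  current <- cov(sets)
  while (current < coverage_goal) {
    best <- NULL
    for (p in seq_along(sets)) {
      miss <- !matched(sets)
      if (!any(miss)) break
      bases <- sort(setdiff(unique(vapply(vm[miss], `[[`, "", p)), sets[[p]]))
      for (b in bases) {
        trial <- sets
        trial[[p]] <- sort(c(trial[[p]], b))
        if (deg(trial) > cap) next
        gain <- cov(trial) - current
        if (gain <= 0) next
        ratio <- gain / (deg(trial) - deg(sets))
        if (is.null(best) || ratio > best$ratio + 1e-12) {
          best <- list(ratio = ratio, sets = trial, cov = cov(trial))
        }
      }
    }
    if (is.null(best)) break
    sets <- best$sets
    current <- best$cov
  }
  seq_out <- paste(vapply(sets, iupac_collapse, ""), collapse = "")
  rec <- primer_record(name, seq_out, orientation = "forward")
  attr(rec, "coverage") <- current
  attr(rec, "goal_met") <- current >= coverage_goal
  rec
}

#' 3'-end discrimination against the exclusion set
#'
#' For each of the last `k` primer positions (counted from the 3'
#' terminus), the fraction of exclusion variants that mismatch there,
#' IUPAC-aware and right-aligned (comparison from the 3' end). The check
#' passes when the terminal 3' base mismatches at least `min_fraction`
#' of the exclusion sequences — a terminal mismatch is what most
#' strongly blocks extension on the host template. Variants differing in
#' length from the primer by more than 2 cannot be compared positionally
#' (edit ambiguity) and are excluded with a flag.
#'
#' @param primer A `primer_record` or IUPAC string (same orientation as
#'   the variants).
#' @param exclusion_variants Character vector of degapped exclusion
#'   window strings, optionally named with abundance counts via
#'   `counts`.
#' @param counts Optional abundance weights (default 1 each).
#' @param k Number of 3'-terminal positions profiled (default 3).
#' @param min_fraction Exclusion fraction the terminal base must
#'   mismatch to pass (default 1 = all).
#' @return List with `fractions` (length k, position 1 = 3' terminus),
#'   `pass`, and `n_refused` (length-incompatible variants).
#' @export
three_prime_mismatch_check <- function(primer, exclusion_variants, counts = NULL,
                                       k = 3, min_fraction = 1) {
  seqp <- if (inherits(primer, "primer_record")) primer$sequence else
    normalize_residues(primer)
  if (is.null(counts)) counts <- rep(1, length(exclusion_variants))
  stopifnot(length(counts) == length(exclusion_variants))
  ok <- abs(nchar(exclusion_variants) - nchar(seqp)) <= 2
  n_refused <- sum(counts[!ok])
  ev <- exclusion_variants[ok]
  cw <- counts[ok]
  if (length(ev) == 0) {
    warning("no exclusion variant is length-compatible with the primer",
            call. = FALSE)
    return(list(fractions = rep(NA_real_, k), pass = NA, n_refused = n_refused))
  }
  pc <- seq_chars(seqp)
  np <- length(pc)
  fr <- vapply(seq_len(k), function(j) {
    if (j > np) return(NA_real_)
    pchar <- pc[np - j + 1]
    mism <- vapply(ev, function(v) {
      nv <- nchar(v)
      if (j > nv) return(TRUE)                 # nothing to pair with
      vchar <- substr(v, nv - j + 1, nv - j + 1)
      !iupac_compatible(pchar, vchar)
    }, logical(1))
    sum(cw[mism]) / sum(cw)
  }, numeric(1))
  list(fractions = fr, pass = fr[1] >= min_fraction, n_refused = n_refused)
}

#' Best approximate occurrence of a primer in a reference sequence
#'
#' Slides the primer (and its reverse complement) over the reference
#' and reports the minimum-mismatch hit under Hamming matching with
#' IUPAC-aware primer positions: a reference base matches when it lies
#' in the primer position's ambiguity set. Ties break to the leftmost
#' position, then to the forward strand.
#'
#' @param primer A `primer_record` or IUPAC string.
#' @param reference Gap-free reference sequence (plain DNA).
#' @param max_mm Maximum mismatches searched, 0..2 (default 2).
#' @return List `(position, mismatches, strand)` (position 1-based in
#'   the reference) or NULL when there is no hit within `max_mm`.
#' @export
approximate_occurrence <- function(primer, reference, max_mm = 2) {
  stopifnot(max_mm >= 0, max_mm <= 2)
  seqp <- if (inherits(primer, "primer_record")) primer$sequence else
    normalize_residues(primer)
  reference <- normalize_residues(reference)
  if (nchar(reference) < nchar(seqp)) return(NULL)
  subj <- Biostrings::DNAString(reference)
  pats <- list(forward = Biostrings::DNAString(seqp),
               reverse = Biostrings::DNAString(reverse_complement(seqp)))
  best <- NULL
  for (strand in names(pats)) {
    for (mm in 0:max_mm) {
      if (!is.null(best) && best$mismatches < mm) break
      hits <- Biostrings::matchPattern(pats[[strand]], subj, max.mismatch = mm,
                                       fixed = "subject")
      if (length(hits) == 0) next
      cand <- list(position = Biostrings::start(hits)[1], mismatches = mm,
                   strand = strand)
      if (is.null(best) ||
          cand$mismatches < best$mismatches ||
          (cand$mismatches == best$mismatches && cand$position < best$position)) {
        best <- cand
      }
      break   # lowest mm for this strand found
    }
  }
  best
}

#' In-silico coverage of a reference set
#'
#' The fraction of reference sequences containing a binding site for
#' the primer (either strand) within 0, 1 and 2 mismatches; cumulative
#' ("summative") by construction.
#'
#' @param primer A `primer_record` or IUPAC string.
#' @param references Character vector (or `DNAStringSet`) of reference
#'   sequences.
#' @param max_mm Deepest threshold evaluated (default 2).
#' @return A `coverage_result`: numeric `cov` with entries `mm0`, `mm1`,
#'   `mm2` and the number of references `n`.
#' @export
coverage_profile <- function(primer, references, max_mm = 2) {
  references <- as.character(references)
  stopifnot(length(references) >= 1)
  mm <- vapply(references, function(r) {
    hit <- approximate_occurrence(primer, r, max_mm = max_mm)
    if (is.null(hit)) Inf else hit$mismatches
  }, numeric(1))
  cov <- vapply(0:max_mm, function(k) mean(mm <= k), numeric(1))
  structure(list(cov = stats::setNames(cov, paste0("mm", 0:max_mm)),
                 n = length(references)),
            class = "coverage_result")
}

#' Apply the primer selection criteria
#'
#' The four criteria used to shortlist candidates: (1) at least 80%
#' coverage of the target reference set at zero or one mismatch,
#' (2) a 3'-end mismatch against the exclusion set, (3) GC content
#' between 40 and 60% (inclusive), (4) a length of approximately 20 bp
#' (20 +/- `length_tol`). The verdict is their conjunction.
#'
#' @param primer A `primer_record`.
#' @param coverage A [coverage_profile()] result over the target
#'   references.
#' @param three_prime_pass Logical from [three_prime_mismatch_check()].
#' @param min_cov1 Coverage floor at <=1 mismatch (default 0.80).
#' @param gc_range Inclusive GC bounds (default c(0.40, 0.60)).
#' @param length_target,length_tol Length criterion (default 20 +/- 3).
#' @return List of per-criterion booleans and `pass`.
#' @export
apply_selection_criteria <- function(primer, coverage, three_prime_pass,
                                     min_cov1 = 0.80, gc_range = c(0.40, 0.60),
                                     length_target = 20, length_tol = 3) {
  stopifnot(inherits(primer, "primer_record"))
  cov1 <- coverage$cov[["mm1"]]
  len <- nchar(primer$sequence)
  out <- list(
    coverage = cov1 >= min_cov1,
    three_prime = isTRUE(three_prime_pass),
    gc = primer$gc_fraction >= gc_range[1] & primer$gc_fraction <= gc_range[2],
    length = abs(len - length_target) <= length_tol)
  out$pass <- all(unlist(out))
  out
}

# longest common substring length (literal character match)
longest_common_substring <- function(a, b) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  best <- 0L
  prev <- integer(length(cb))
  for (i in seq_along(ca)) {
    cur <- integer(length(cb))
    for (j in seq_along(cb)) {
      if (ca[i] == cb[j]) {
        cur[j] <- if (j == 1) 1L else prev[j - 1] + 1L
        if (cur[j] > best) best <- cur[j]
      }
    }
    prev <- cur
  }
  best
}

# longest suffix of `a` occurring as a substring of `b`
longest_anchored_suffix <- function(a, b) {
  for (L in seq(min(nchar(a), nchar(b)), 1)) {
    suf <- substr(a, nchar(a) - L + 1, nchar(a))
    if (grepl(suf, b, fixed = TRUE)) return(L)
  }
  0L
}

#' Primer-pair compatibility report
#'
#' Screens a forward/reverse pair for co-amplification suitability:
#' melting-temperature difference, predicted amplicon length on the
#' ungapped target consensus, and a heterodimer heuristic — the length
#' of the longest perfect reverse-complement match between substrings of
#' the two primers, with the 3'-anchored variant (a primer's 3' suffix
#' complementary to the partner) reported separately since 3' duplexes
#' are the most inhibitory. This sequence-level heuristic stands in for
#' a full thermodynamic duplex model.
#'
#' @param fw,rv `primer_record`s (forward and reverse).
#' @param fw_start 1-based coordinate of the forward primer's 5' end on
#'   the ungapped consensus.
#' @param rv_end 1-based coordinate of the reverse primer's 3'-most
#'   consensus position (the downstream end of its binding site).
#' @param max_delta_tm Pass threshold on |Tm difference| in degrees C
#'   (default 5).
#' @param max_three_prime_comp 3'-anchored complementarity must stay
#'   strictly below this many bp (default 5).
#' @return A `pair_report` list: `delta_tm`, `predicted_amplicon_bp`,
#'   `heterodimer_score`, `three_prime_comp`, `pass`.
#' @export
pair_compatibility <- function(fw, rv, fw_start, rv_end,
                               max_delta_tm = 5, max_three_prime_comp = 5) {
  stopifnot(inherits(fw, "primer_record"), inherits(rv, "primer_record"))
  amplicon <- rv_end - fw_start + 1
  if (amplicon <= 0) {
    stop("reverse site (end ", rv_end, ") must lie downstream of the forward ",
         "site (start ", fw_start, ")", call. = FALSE)
  }
  rc_rv <- reverse_complement(rv$sequence)
  rc_fw <- reverse_complement(fw$sequence)
  het <- longest_common_substring(fw$sequence, rc_rv)
  anchored <- max(longest_anchored_suffix(fw$sequence, rc_rv),
                  longest_anchored_suffix(rv$sequence, rc_fw))
  delta <- abs(fw$tm_celsius - rv$tm_celsius)
  structure(list(forward = fw, reverse = rv, delta_tm = delta,
                 predicted_amplicon_bp = as.integer(amplicon),
                 heterodimer_score = het, three_prime_comp = anchored,
                 pass = delta <= max_delta_tm && anchored < max_three_prime_comp),
            class = "pair_report")
}

#' @export
print.pair_report <- function(x, ...) {
  cat("<pair_report> ", x$forward$name, " + ", x$reverse$name, "\n",
      "  delta Tm ", sprintf("%.2f", x$delta_tm), " C; amplicon ",
      x$predicted_amplicon_bp, " bp; heterodimer run ", x$heterodimer_score,
      " bp (3'-anchored ", x$three_prime_comp, " bp); ",
      if (x$pass) "PASS" else "FAIL", "\n", sep = "")
  invisible(x)
}
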