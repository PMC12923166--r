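# Independent oracles and small fixture builders used across the suite.

# Wagner-Fischer dynamic-programming Levenshtein distance, written
# independently of the package's edit-distance path.
levenshtein_dp <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  if (n == 0) return(m)
  if (m == 0) return(n)
  prev <- 0:m
  for (i in 1:n) {
    cur <- integer(m + 1)
    cur[1] <- i
    for (j in 1:m) {
      cost <- if (ca[i] == cb[j]) 0L else 1L
      cur[j + 1] <- min(prev[j + 1] + 1L, cur[j] + 1L, prev[j] + cost)
    }
    prev <- cur
  }
  prev[m + 1]
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# flat Dirichlet draw over the 5 mismatch bins
random_profile <- function() {
  g <- stats::rgamma(5, shape = 1)
  g / sum(g)
}

# write a small aligned FASTA and return its path
write_fasta <- function(seqs, ids = sprintf("seq%02d", seq_along(seqs)),
                        path = tempfile(fileext = ".fasta")) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

# standard multi-site fixture: planted windows spanning the score range
planted_span_sites <- function() {
  list(
    planted_site(51,  exclusion_fractions = c("0" = 0.8, "1" = 0.2)),   # 0.10
    planted_site(151, exclusion_fractions = c("0" = 0.6, "1" = 0.2, "4" = 0.2)), # 0.30
    planted_site(251, exclusion_fractions = c("0" = 0.4, "1" = 0.2, "4" = 0.4)), # 0.50
    planted_site(351, exclusion_fractions = c("0" = 0.2, "1" = 0.2, "4" = 0.6)), # 0.70
    planted_site(451, target_fractions = c("0" = 0.9, "1" = 0.1),
                 exclusion_fractions = c("2" = 0.1, "3" = 0.2, "4" = 0.7)))      # 0.95
}
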