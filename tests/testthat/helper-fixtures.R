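# build a repeat pair object with controlled mismatch structure:
# n_adenine mismatch columns carry A in the template copy, n_other columns
# differ without an adenine on either side
make_pair <- function(len, n_adenine, n_other, seed = 101, orientation = "direct") {
  set.seed(seed)
  base_a <- sample(c("C", "G", "T"), len, replace = TRUE)
  cols <- sample(len, n_adenine + n_other)
  a_cols <- cols[seq_len(n_adenine)]
  o_cols <- setdiff(cols, a_cols)
  tr <- base_a
  tr[a_cols] <- "A"
  vr <- tr
  vr[a_cols] <- vapply(a_cols, function(i) sample(c("C", "G", "T"), 1), character(1))
  for (i in o_cols) vr[i] <- sample(setdiff(c("C", "G", "T"), tr[i]), 1)
  list(record_id = "x", copyA_start = 0L, copyA_end = len,
       copyB_start = 1000L, copyB_end = 1000L + len,
       orientation = orientation, aligned_len = len,
       n_mismatch = n_adenine + n_other,
       alnA = paste(tr, collapse = ""), alnB = paste(vr, collapse = ""))
}


# plant two repeat copies (optionally substituted / inverted) in a random
# background and return the record plus planted coordinates
plant_repeat <- function(len = 114, n_sub = 12, gap = 2000, inverted = FALSE,
                         seed = 77, bg = 6000) {
  set.seed(seed)
  tr <- strsplit(random_dna(len), "")[[1]]
  a_pos <- sample(8:(len - 8), n_sub)  # interior substitutions: clean edges
  tr[a_pos] <- "A"
  vr <- tr
  vr[a_pos] <- vapply(a_pos, function(i) sample(c("C", "G", "T"), 1), character(1))
  copyA <- paste(tr, collapse = "")
  copyB <- paste(vr, collapse = "")
  if (inverted) copyB <- revcomp(copyB)
  s <- random_dna(bg)
  p1 <- 1000L; p2 <- p1 + len + gap
  seqn <- paste0(substr(s, 1, p1), copyA,
                 substr(s, p1 + len + 1, p2), copyB,
                 substr(s, p2 + len + 1, bg))
  list(seq = seqn, a = c(p1, p1 + len), b = c(p2, p2 + len))
}

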