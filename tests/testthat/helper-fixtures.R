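# Shared fixture builders. Everything is generated in code at test time.

# Tiny hand-written cohort files (3 participants) in a temp dir.
write_tiny_cohort_files <- function(dir = tempfile("coh")) {
  dir.create(dir)
  phe <- data.frame(participant_id = c("A1", "A2", "A3"),
                    age = c(40, 52, 13), sex = c("male", "female", "male"),
                    carrier = c(1L, 0L, 0L),
                    QRS_v1 = c(92.5, 101.0, NA), QRS_v2 = c(93.1, NA, 88.0),
                    HR_v1 = c(64, 72, 80), HR_v2 = c(66, 70, 78))
  flg <- data.frame(participant_id = c("A1", "A2", "A3"),
                    HF_v1 = c(0L, 1L, 0L), HF_v2 = c(0L, 0L, 0L),
                    atrial_fibrillation_v1 = c(0L, 0L, 0L),
                    atrial_fibrillation_v2 = c(0L, 0L, 0L),
                    cause_of_death = c(NA, NA, NA))
  fam <- c("FAM1 A1 0 0 1 -9", "FAM1 A2 0 0 2 -9", "FAM1 A3 A1 A2 1 -9")
  write.table(phe, file.path(dir, "phe.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  write.table(flg, file.path(dir, "flg.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  writeLines(fam, file.path(dir, "ped.fam"))
  dir
}

# A small simulated cohort shared by several test files (computed once).
small_sim <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      cfg <- sim_config(n_individuals = 1500, founder_allele_freq = 0.012,
                        n_genome_variants = 200, n_region_variants = 120,
                        seed = 42)
      val <<- simulate_cohort(cfg)
    }
    val
  }
})

# FAM with known relationships: two founder parents, two full sibs,
# a half sib via a second mate, and an unrelated singleton.
six_member_fam <- function() {
  data.frame(
    family_id = c(rep("F1", 5), "S1"),
    participant_id = c("dad", "mum", "kid1", "kid2", "half", "lone"),
    father_id = c(NA, NA, "dad", "dad", "dad", NA),
    mother_id = c(NA, NA, "mum", "mum", NA, NA),
    sex = c("male", "female", "male", "female", "male", "female"),
    phenotype = -9, stringsAsFactors = FALSE)
}

# Direct O(n^2) path-free kinship oracle via allele-dropping simulation.
gene_drop_kinship <- function(fam, reps = 20000) {
  n <- nrow(fam)
  fa <- match(fam$father_id, fam$participant_id)
  mo <- match(fam$mother_id, fam$participant_id)
  ord <- order(!is.na(fa) | !is.na(mo))  # founders first (works for 2 gens)
  acc <- matrix(0, n, n)
  for (r in seq_len(reps)) {
    al <- matrix(0L, n, 2)
    nxt <- 1L
    for (i in ord) {
      if (is.na(fa[i]) && is.na(mo[i])) {
        al[i, ] <- c(nxt, nxt + 1L); nxt <- nxt + 2L
      } else {
        a1 <- if (!is.na(fa[i])) al[fa[i], sample(2, 1)] else {
          nxt <- nxt + 1L; nxt - 1L }
        a2 <- if (!is.na(mo[i])) al[mo[i], sample(2, 1)] else {
          nxt <- nxt + 1L; nxt - 1L }
        al[i, ] <- c(a1, a2)
      }
    }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      acc[i, j] <- acc[i, j] +
        mean(outer(al[i, ], al[j, ], "==")) / 1
    }
  }
  acc / reps
}
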