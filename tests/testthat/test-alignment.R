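test_that("identical sequences align residue-by-residue at 100% identity", {
  a <- global_align("ACDK", "ACDK")
  expect_equal(unname(a$pairs), cbind(1:4, 1:4))
  expect_equal(a$identity_pct, 100)
  expect_equal(a$similarity_pct, 100)
})

test_that("alignment score and traceback match exhaustive enumeration", {
  sub <- mm_matrix()
  p <- align_params(submat = sub, gap_open = 2, gap_extend = 1)

  # the overhang example, explicitly
  a <- global_align("KKACDE", "ACDE", p)
  expect_equal(a$score,
               enumerate_align_score("KKACDE", "ACDE", sub, 2, 1))
  expect_equal(score_alignment_columns(a, "KKACDE", "ACDE", sub, 2, 1),
               a$score)
  expect_equal(unname(a$pairs), cbind(3:6, 1:4))

  # random battery at small length: optimal score, optimal traceback,
  # strictly increasing pairs
  set.seed(101)
  for (k in 1:60) {
    sa <- random_aa(sample(1:6, 1))
    sb <- random_aa(sample(1:6, 1))
    open <- sample(c(0.5, 1, 2, 5), 1)
    ext <- sample(c(0.25, 0.5, 1), 1)
    pp <- align_params(submat = sub, gap_open = open, gap_extend = ext)
    al <- global_align(sa, sb, pp)
    opt <- enumerate_align_score(sa, sb, sub, open, ext)
    expect_equal(al$score, opt, tolerance = 1e-12,
                 label = sprintf("score(%s,%s)", sa, sb))
    expect_equal(score_alignment_columns(al, sa, sb, sub, open, ext), opt,
                 tolerance = 1e-12)
    if (nrow(al$pairs) > 1) {
      expect_true(all(diff(al$pairs[, 1]) > 0))
      expect_true(all(diff(al$pairs[, 2]) > 0))
    }
  }
})

test_that("BLOSUM62 defaults reproduce the hand-summed gapless score", {
  b62 <- mirenrich:::get_submatrix("BLOSUM62")
  a <- global_align("KAC", "KEC")
  hand <- b62["K", "K"] + b62["A", "E"] + b62["C", "C"]
  # the 3 candidate shapes: gapless beats any single-gap shape at open 10
  expect_equal(a$score, hand)
  expect_equal(nrow(a$pairs), 3L)
})

test_that("alignment score agrees with an independent implementation", {
  skip_if_not_installed("Biostrings")
  set.seed(77)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  b62 <- mirenrich:::get_submatrix("BLOSUM62")
  for (k in 1:10) {
    sa <- random_aa(sample(10:40, 1), aa20)
    sb <- random_aa(sample(10:40, 1), aa20)
    ours <- global_align(sa, sb)$score
    ref <- Biostrings::pairwiseAlignment(
      sa, sb, substitutionMatrix = b62, gapOpening = 10,
      gapExtension = 0.5, type = "global", scoreOnly = TRUE)
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("identity and similarity count columns as defined", {
  ten <- "ACDEFGHIKL"
  a <- global_align(ten, ten)
  expect_equal(a$identity_pct, 100)

  # gapless 5/10 matches, mismatched pairs negative in BLOSUM62 (K vs D = -1)
  s1 <- "AAAAAKKKKK"; s2 <- "AAAAADDDDD"
  a2 <- global_align(s1, s2)
  expect_equal(nrow(a2$pairs), 10L)
  expect_equal(a2$identity_pct, 50)
  expect_equal(a2$similarity_pct, 50)

  # internal gap column enters the denominator: hand-count on a 6-column toy
  sub <- mm_matrix()
  p <- align_params(submat = sub, gap_open = 1, gap_extend = 0.5)
  a3 <- global_align("ACDKEA", "ACKEA", p)
  # expected: ACDKEA / AC-KEA -> 6 columns, 5 matches
  expect_equal(nrow(a3$pairs), 5L)
  expect_equal(a3$aligned_cols, 6L)
  expect_equal(a3$identity_pct, 100 * 5 / 6)
})

test_that("Kabsch superposition recovers rigid transforms exactly", {
  set.seed(5)
  A <- matrix(rnorm(30, sd = 5), 10, 3)
  sp <- kabsch_superpose(A, A)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-8)

  B <- sweep(A, 2, c(5, 0, 0), "+")
  sp2 <- kabsch_superpose(A, B)
  expect_equal(sp2$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp2$translation, c(-5, 0, 0), tolerance = 1e-8)

  expect_error(kabsch_superpose(A[1:2, ], A[1:2, ],
                                cbind(1:2, 1:2)), "at least 3")
})

test_that("Kabsch RMSD equals direct minimization over rotations", {
  set.seed(11)
  A <- matrix(rnorm(12, sd = 3), 4, 3)
  R <- random_rotation()
  B <- t(R %*% t(A)) + matrix(rnorm(12, sd = 0.3), 4, 3)
  sp <- kabsch_superpose(B, A)          # fit A onto B
  expect_equal(sp$rmsd, rmsd_by_optim(B, A), tolerance = 1e-5)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-6)
})

test_that("superposition RMSD is invariant to common rigid transforms", {
  set.seed(21)
  A <- matrix(rnorm(45, sd = 4), 15, 3)
  B <- A + matrix(rnorm(45, sd = 0.5), 15, 3)
  base <- kabsch_superpose(A, B)$rmsd
  for (k in 1:5) {
    R <- random_rotation(); tr <- rnorm(3, sd = 10)
    A2 <- t(R %*% t(A)) + matrix(tr, 15, 3, byrow = TRUE)
    B2 <- t(R %*% t(B)) + matrix(tr, 15, 3, byrow = TRUE)
    expect_equal(kabsch_superpose(A2, B2)$rmsd, base, tolerance = 1e-8)
    expect_equal(det(kabsch_superpose(A2, B2)$rotation), 1,
                 tolerance = 1e-6)
  }
})

make_structured_record <- function(id, seqs, xyz = NULL) {
  n <- nchar(seqs)
  if (is.null(xyz)) xyz <- mirenrich:::helix_trace(n)
  domain_record(id, seqs, "BAR", c(1L, n),
                structure = list(xyz = xyz, pos = seq_len(n)))
}

test_that("structural alignment pairs every residue of a self-alignment", {
  set.seed(31)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  r <- make_structured_record("T", random_aa(60, aa20))
  m <- structure_align(r, r)
  expect_equal(nrow(m$pairs), 60L)
  expect_lt(m$rmsd, 1e-8)
  expect_equal(unname(m$pairs[, 1]), unname(m$pairs[, 2]))
})

test_that("structural alignment survives moderate coordinate noise", {
  set.seed(32)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- random_aa(80, aa20)
  tpl <- make_structured_record("T", seqs)
  noisy <- tpl$structure$xyz + matrix(rnorm(240, sd = 0.5), 80, 3)
  R <- random_rotation()
  tgt <- make_structured_record("Q", seqs, xyz = t(R %*% t(noisy)))
  m <- structure_align(tpl, tgt)
  expect_gte(nrow(m$pairs), 0.95 * 80)
})

test_that("structural alignment keeps only the shared rigid segment", {
  set.seed(33)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- random_aa(80, aa20)
  tpl <- make_structured_record("T", seqs)
  # first 72 residues shared; the tail displaced away (a different fold)
  xyz2 <- tpl$structure$xyz
  xyz2[73:80, ] <- xyz2[73:80, ] + matrix(c(20, 15, -10), 8, 3, byrow = TRUE)
  tgt <- make_structured_record("Q", seqs, xyz = xyz2)
  m <- structure_align(tpl, tgt)
  expect_gte(nrow(m$pairs), 40)
  expect_true(all(m$pairs[, 1] <= 72))
})

test_that("segment-wise alignment matches the unsegmented result for one segment", {
  set.seed(34)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  sa <- random_aa(50, aa20); sb <- random_aa(55, aa20)
  ta <- domain_record("A", sa, "BAR")
  tb <- domain_record("B", sb, "BAR")
  seg <- segmented_align(ta, tb, intervals(1, 50))
  full <- global_align(sa, sb)
  expect_equal(unname(seg$pairs), unname(full$pairs))
  expect_error(segmented_align(ta, tb, rbind(intervals(1, 30),
                                             intervals(20, 50))),
               "overlap")
  expect_error(segmented_align(ta, tb, intervals()), "empty segment")
})

test_that("segment-wise superposition beats a single rigid fit across a hinge", {
  set.seed(35)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- random_aa(80, aa20)
  tpl <- make_structured_record("T", seqs)
  # rotate the second half about a hinge at residue 40
  xyz2 <- tpl$structure$xyz
  hinge <- xyz2[40, ]
  ang <- 35 * pi / 180
  R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  xyz2[41:80, ] <- t(R %*% t(sweep(xyz2[41:80, ], 2, hinge))) +
    matrix(hinge, 40, 3, byrow = TRUE)
  tgt <- make_structured_record("Q", seqs, xyz = xyz2)
  global_fit <- kabsch_superpose(tpl$structure$xyz, xyz2)
  segs <- rbind(intervals(1, 40), intervals(41, 80))
  m <- segmented_align(tpl, tgt, segs)
  expect_true(all(m$segment_rmsd < global_fit$rmsd))
  expect_true(all(diff(m$pairs[, 1]) > 0))
  expect_true(all(diff(m$pairs[, 2]) > 0))
})

test_that("identity clustering excludes divergent members, single linkage chains", {
  set.seed(41)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  tpl_seq <- random_aa(100, aa20)
  mutate_at <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    for (p in pos) ch[p] <- sample(setdiff(aa20, ch[p]), 1)
    paste(ch, collapse = "")
  }
  seq_a <- mutate_at(tpl_seq, 1:40)     # 60% to template
  seq_b <- mutate_at(seq_a, 41:55)      # 85% to A, 45% to template
  recs <- list(domain_record("T", tpl_seq, "BAR"),
               domain_record("A", seq_a, "BAR"),
               domain_record("B", seq_b, "BAR"))

  cl <- cluster_by_identity(recs, template_id = "T")
  expect_gte(cl$identity_to_template[["A"]], 57)
  expect_lt(cl$identity_to_template[["B"]], 50)
  expect_setequal(cl$cluster, c("T", "A", "B"))  # B joins through A
  expect_length(cl$excluded, 0L)

  cl2 <- cluster_by_identity(recs, align_params(cluster_mode = "template"),
                             template_id = "T")
  expect_setequal(cl2$cluster, c("T", "A"))
  expect_equal(cl2$excluded, "B")

  # two identical sequences: one cluster, none excluded
  cl3 <- cluster_by_identity(list(domain_record("X", tpl_seq, "BAR"),
                                  domain_record("Y", tpl_seq, "BAR")))
  expect_setequal(cl3$cluster, c("X", "Y"))
  expect_length(cl3$excluded, 0L)

  # shuffled sequence drops below the threshold and is excluded
  shuf <- paste(sample(strsplit(tpl_seq, "")[[1]]), collapse = "")
  cl4 <- cluster_by_identity(list(domain_record("T", tpl_seq, "BAR"),
                                  domain_record("S", shuf, "BAR")),
                             template_id = "T")
  expect_equal(cl4$excluded, "S")
})

test_that("C2 subtype assignment follows the closer template and flags degenerates", {
  set.seed(51)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ta <- domain_record("C2A", random_aa(120, aa20), "C2")
  tb <- domain_record("C2B", random_aa(120, aa20), "C2")

  self <- assign_c2_subtype(ta, ta, tb)
  expect_equal(self$subtype, "C2A-like")
  expect_equal(self$similarity_a, 100)

  # built 70% from the C2B template
  chb <- strsplit(tb$sequence, "")[[1]]
  mut <- sample(120, 36)
  for (p in mut) chb[p] <- sample(setdiff(aa20, chb[p]), 1)
  near_b <- domain_record("Q", paste(chb, collapse = ""), "C2")
  expect_equal(assign_c2_subtype(near_b, ta, tb)$subtype, "C2B-like")

  # low-complexity sequence is degenerate
  lowc <- domain_record("L", strrep("AG", 60), "C2")
  expect_equal(assign_c2_subtype(lowc, ta, tb)$subtype, "degenerate")

  expect_warning(tie <- assign_c2_subtype(ta, ta, ta), "tie")
  expect_equal(tie$subtype, "C2A-like")
})

test_that("alignments export as gapped FASTA and TSV pair lists", {
  a <- global_align("KKACDE", "ACDE",
                    align_params(submat = mm_matrix(), gap_open = 2,
                                 gap_extend = 1))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_alignment_fasta(a, "KKACDE", "ACDE", c("s1", "s2"), f)
  back <- read_fasta(f)
  expect_equal(back$s1, "KKACDE")
  expect_equal(back$s2, "--ACDE")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_alignment_tsv(a, tf)
  tab <- read.delim(tf)
  expect_equal(tab$posA, 3:6)
  expect_equal(tab$posB, 1:4)
})
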