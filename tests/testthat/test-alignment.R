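fasta_lines <- c(">kinA", "MKV-LD", ">kinB", "MKVALD", ">kinC", "MKVALD")

test_that("FASTA parsing round-trips and preserves order", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(fasta_lines, f)
  msa <- read_alignment(f)
  expect_identical(msa$ids, c("kinA", "kinB", "kinC"))
  expect_identical(nchar(msa$seqs), rep(6L, 3))

  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_alignment_fasta(msa, f2)
  expect_identical(read_alignment(f2), msa)
})

test_that("FASTA parsing agrees with Biostrings on a round-trip", {
  withr::with_seed(19, {
    seqs <- vapply(1:4, function(i)
      paste(sample(c("A", "C", "D", "-", "K"), 30, replace = TRUE), collapse = ""), "")
  })
  f <- withr::local_tempfile(fileext = ".fasta")
  write_alignment_fasta(new_msa(paste0("id", 1:4), seqs), f)
  msa <- read_alignment(f)
  ref <- Biostrings::readAAStringSet(f)
  expect_identical(msa$ids, names(ref))
  expect_identical(msa$seqs, unname(as.character(ref)))
})

test_that("ragged alignments and duplicate ids are rejected by name", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "MKVALDPQRS", ">b", "MKVALDPQR"), f)
  expect_error(read_alignment(f), "b", class = "kinoflex_format_error")
  expect_error(new_msa(c("a", "a"), c("MK", "MK")), "duplicate",
               class = "kinoflex_validation_error")
})

test_that("interleaved Clustal blocks concatenate to the FASTA equivalent", {
  withr::with_seed(21, {
    aas <- c("A", "C", "D", "E", "F", "-")
    seqs <- vapply(1:3, function(i)
      paste(sample(aas, 80, replace = TRUE, prob = c(rep(0.18, 5), 0.1)),
            collapse = ""), "")
  })
  ids <- c("seq1", "seq2", "seq3")
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_alignment_fasta(new_msa(ids, seqs), fa)
  cl <- withr::local_tempfile(fileext = ".aln")
  blocks <- c("CLUSTAL W multiple sequence alignment", "")
  for (start in seq(1, 80, by = 60)) {
    chunk <- substr(seqs, start, min(start + 59, 80))
    blocks <- c(blocks, paste(formatC(ids, width = 10, flag = "-"), chunk), "")
  }
  writeLines(blocks, cl)
  expect_identical(read_alignment(cl, format = "clustal")$seqs,
                   read_alignment(fa, format = "fasta")$seqs)
})

test_that("column retention follows the all-ungapped rule", {
  # gap-free: identity mapping, all columns retained
  msa <- new_msa(c("x", "y"), c("MKVAL", "MKVAL"))
  map <- build_column_map(msa, list(x = 1:5, y = 11:15))
  expect_identical(map$retained_columns, 1:5)
  expect_identical(map$map$residue_id[map$map$kinase == "y"], 11:15)

  # one gap in one sequence at column 5 drops exactly that column
  msa2 <- new_msa(c("x", "y"), c("MKVAL", "MKVA-"))
  map2 <- build_column_map(msa2, list(x = 1:5, y = 11:14))
  expect_identical(map2$retained_columns, 1:4)

  # random gap patterns match a brute-force per-column loop
  withr::with_seed(31, {
    for (rep in 1:10) {
      mat <- matrix(sample(c("A", "-"), 4 * 12, replace = TRUE, prob = c(0.85, 0.15)),
                    4, 12)
      seqs <- apply(mat, 1, paste, collapse = "")
      ids <- paste0("s", 1:4)
      rids <- lapply(seq_len(4), function(i) which(mat[i, ] != "-"))
      names(rids) <- ids
      expected <- which(vapply(seq_len(12), function(j) all(mat[, j] != "-"), TRUE))
      if (any(vapply(rids, length, 0L) == 0)) next
      map <- build_column_map(new_msa(ids, seqs), rids)
      expect_identical(map$retained_columns, as.integer(expected))
    }
  })
})

test_that("adding a gap never increases the retained column set", {
  msa <- new_msa(c("x", "y", "z"), c("MKVALD", "MKVALD", "MKVALD"))
  base <- build_column_map(msa, list(x = 1:6, y = 1:6, z = 1:6))$retained_columns
  msa_gap <- new_msa(c("x", "y", "z"), c("MKVALD", "MK-ALD", "MKVALD"))
  gapped <- build_column_map(msa_gap, list(x = 1:6, y = c(1:2, 4:6), z = 1:6))$retained_columns
  expect_true(all(gapped %in% base))
  expect_lt(length(gapped), length(base) + 1)
})

test_that("length mismatches raise a correspondence error with both lengths", {
  msa <- new_msa(c("x"), c("MKVAL"))
  expect_error(build_column_map(msa, list(x = 1:4)), "5.*4|4.*5",
               class = "kinoflex_format_error")
})

test_that("matrix assembly places profile values and reports failures", {
  msa <- new_msa(c("p", "q"), c("MKV", "MKV"))
  map <- build_column_map(msa, list(p = c(3L, 4L, 5L), q = c(7L, 8L, 9L)))
  profiles <- list(
    p = tibble::tibble(residue_id = 3:5, rmsf = c(0.5, 0.7, 0.9)),
    q = tibble::tibble(residue_id = 7:9, rmsf = c(1.1, 1.3, 1.5))
  )
  panel <- assemble_matrix(profiles, map, c(p = "active", q = "inactive"))
  expect_identical(names(panel), c("kinase", "label", "c1", "c2", "c3"))
  expect_equal(unlist(panel[panel$kinase == "q", c("c1", "c2", "c3")],
                      use.names = FALSE), c(1.1, 1.3, 1.5))
  expect_false(anyNA(panel))

  profiles$q <- profiles$q[-2, ]   # remove residue 8
  expect_error(assemble_matrix(profiles, map, c(p = "active", q = "inactive")),
               "q.*residue 8", class = "kinoflex_assembly_error")
})

test_that("row order of assembly follows the map, values unchanged on permutation", {
  msa1 <- new_msa(c("p", "q"), c("MK", "MK"))
  msa2 <- new_msa(c("q", "p"), c("MK", "MK"))
  profiles <- list(p = tibble::tibble(residue_id = 1:2, rmsf = c(0.2, 0.4)),
                   q = tibble::tibble(residue_id = 1:2, rmsf = c(0.6, 0.8)))
  labels <- c(p = "active", q = "inactive")
  a <- assemble_matrix(profiles, build_column_map(msa1, profiles |> lapply(`[[`, "residue_id")), labels)
  b <- assemble_matrix(profiles, build_column_map(msa2, profiles |> lapply(`[[`, "residue_id")), labels)
  expect_identical(a$kinase, rev(b$kinase))
  expect_equal(dplyr::arrange(a, .data$kinase), dplyr::arrange(b, .data$kinase))
})

test_that("activity labelling thresholds the series mean", {
  expect_identical(label_from_activity(rep(1, 10)), "active")
  expect_identical(label_from_activity(rep(0, 10)), "inactive")
  # a kinase spending 17.7% of the trajectory in active conformations
  expect_identical(label_from_activity(rep(0.177, 50)), "inactive")
  expect_identical(label_from_activity(c(0.6, 0.4)), "active") # mean 0.5 >= cut
  expect_error(label_from_activity(c(0.5, 1.2)), "series",
               class = "kinoflex_validation_error")
  expect_error(label_from_activity(numeric(0)), "series",
               class = "kinoflex_validation_error")
})

test_that("end-to-end: profiles through a gap-free MSA reproduce the panel", {
  spec <- panel_spec(n_active = 3, n_inactive = 3, n_columns = 6, signal_column = 2,
                     corr_block = integer(0), seed = 17)
  panel <- gen_fluctuation_panel(spec)
  ids <- panel$kinase
  profiles <- lapply(seq_along(ids), function(i) {
    tibble::tibble(residue_id = 1:6,
                   rmsf = as.numeric(unlist(panel[i, paste0("c", 1:6)])))
  })
  names(profiles) <- ids
  msa <- new_msa(ids, rep(paste(rep("A", 6), collapse = ""), length(ids)))
  map <- build_column_map(msa, lapply(profiles, `[[`, "residue_id"))
  rebuilt <- assemble_matrix(profiles, map, setNames(panel$label, ids))
  expect_equal(as.data.frame(rebuilt), as.data.frame(panel)[names(rebuilt)])
})
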