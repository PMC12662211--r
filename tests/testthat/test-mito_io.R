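# Reference handling, variant calling, masking, heteroplasmy.

test_that("load_reference accepts a single valid record and rejects bad input", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">rCRS synthetic", REF$sequence), fa)
  ref <- load_reference(fa)
  expect_s3_class(ref, "mito_reference")
  expect_identical(ref$length, 16569L)
  expect_identical(ref$name, "rCRS")

  two <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACGT"), two)
  expect_error(load_reference(two), "exactly one record")

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "ACG?T"), bad)
  expect_error(load_reference(bad), "non-IUPAC")

  short <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">rCRS", "ACGT"), short)
  expect_error(load_reference(short), "16569")
})

test_that("region assignment partitions 1..16569 into coding and control", {
  reg <- mito_region(1:16569)
  expect_identical(sum(reg == "coding"), 16023L - 577L + 1L)
  expect_identical(which(reg == "coding"), 577:16023)
  expect_setequal(which(reg == "control"), c(1:576, 16024:16569))
  expect_error(mito_region(0))
  expect_error(mito_region(16570))
})

test_that("call_variants: identity, single substitution, N handling", {
  expect_identical(nrow(call_variants(REF$sequence, REF)$variants), 0L)

  s <- REF$sequence
  rb <- ref_base(769)
  substr(s, 769, 769) <- transition_partner[[rb]]
  p <- call_variants(s, REF, "s1")
  expect_identical(p$variants$position, 769L)
  expect_identical(p$variants$ref, rb)
  expect_identical(p$variants$vclass, "transition")
  expect_identical(p$variants$region, "coding")

  # N generates no variant and is excluded from the identity denominator
  substr(s, 100, 100) <- "N"
  p2 <- call_variants(s, REF, "s2")
  expect_identical(p2$variants$position, 769L)

  # a clearly non-mitogenome input is rejected
  junk <- paste(rep("A", 16569), collapse = "")
  expect_error(call_variants(junk, REF), "not a mitogenome")
})

test_that("transversion and control-region annotation are set", {
  pos <- 16300L
  rb <- ref_base(pos)
  alt <- setdiff(c("A", "C", "G", "T"),
                 c(rb, transition_partner[[rb]]))[1L]
  s <- REF$sequence
  substr(s, pos, pos) <- alt
  v <- call_variants(s, REF)$variants
  expect_identical(v$vclass, "transversion")
  expect_identical(v$region, "control")
})

test_that("indels are placed at the 3'-most equivalent position", {
  # build a homopolymer run so the insertion is realizable at several
  # offsets, then check against brute-force enumeration of equivalent
  # placements
  s <- REF$sequence
  run_start <- 5000L
  substr(s, run_start - 1L, run_start + 5L) <- "CAAAAAG"  # bounded A-run
  ref2 <- reference_genome("custom", s)
  sample_chars <- strsplit(s, "")[[1L]]
  sample_seq <- paste(c(sample_chars[1:(run_start + 1L)], "A",
                        sample_chars[(run_start + 2L):length(sample_chars)]),
                      collapse = "")
  p <- call_variants(sample_seq, ref2)
  ins <- p$variants[p$variants$vclass == "insertion", ]
  expect_identical(nrow(ins), 1L)
  # brute force: all positions after which inserting "A" reproduces the
  # sample; the convention takes the maximum
  cand <- vapply(seq(run_start - 2L, run_start + 8L), function(q) {
    trial <- paste(append(sample_chars, "A", after = q), collapse = "")
    identical(trial, sample_seq)
  }, TRUE)
  expect_identical(ins$position,
                   max(seq(run_start - 2L, run_start + 8L)[cand]))

  # deletion inside the run is also right-shifted
  del_seq <- paste(sample_chars[-(run_start + 1L)], collapse = "")
  pd <- call_variants(del_seq, ref2)
  del <- pd$variants[pd$variants$vclass == "deletion", ]
  expect_identical(nrow(del), 1L)
  expect_identical(del$position, run_start + 4L)  # last base of the run
})

test_that("apply_variants inverts call_variants for substitution profiles", {
  set.seed(11)
  for (rep in 1:5) {
    pos <- sample(setdiff(1:16569, 16180:16195), 12)
    s <- REF$sequence
    for (q in pos) {
      alt <- setdiff(c("A", "C", "G", "T"), ref_base(q))[sample(3, 1)]
      substr(s, q, q) <- alt
    }
    p <- call_variants(s, REF)
    expect_identical(apply_variants(p, REF), s)
  }
})

test_that("apply_mask removes listed sites, counts them, and is idempotent", {
  p <- variant_profile("x", variant_table(
    position = c(309L, 769L), ref = c("-", ref_base(769)),
    alt = c("C", transition_partner[[ref_base(769)]])))
  m <- apply_mask(p)
  expect_identical(m$variants$position, 769L)
  expect_identical(m$masked_removed, 1L)
  m2 <- apply_mask(m)
  expect_identical(m2$variants, m$variants)
  expect_identical(m2$masked_removed, m$masked_removed)

  # hotspot substitution 16182 A->C removed under the default mask
  p2 <- variant_profile("y", variant_table(16182L, ref_base(16182), "C"))
  expect_identical(nrow(apply_mask(p2)$variants), 0L)
  # 16519 removed whatever the allele
  p3 <- variant_profile("z", variant_table(
    16519L, ref_base(16519), transition_partner[[ref_base(16519)]]))
  expect_identical(nrow(apply_mask(p3)$variants), 0L)
  # an indel at a non-listed position survives
  p4 <- variant_profile("w", variant_table(5000L, "-", "T"))
  expect_identical(nrow(apply_mask(p4)$variants), 1L)

  empty <- apply_mask(variant_profile("e"))
  expect_identical(nrow(empty$variants), 0L)
  expect_identical(empty$masked_removed, 0L)
})

test_that("default mask contains the documented exclusions", {
  m <- default_site_mask()
  expect_setequal(m$excluded_indel_positions,
                  c(309L, 315L, 515:522, 16193L))
  expect_setequal(m$excluded_positions, c(16182L, 16183L, 16519L))
  expect_identical(m$excluded_alleles$allele, c("C", "C"))
})

test_that("heteroplasmy calls follow the inclusive 31-70% band", {
  expect_true(call_heteroplasmy(c(A = 0.50, G = 0.50)))
  expect_false(call_heteroplasmy(c(A = 0.71, G = 0.29)))
  expect_true(call_heteroplasmy(c(A = 0.31, G = 0.69)))
  expect_false(call_heteroplasmy(c(A = 0.70, G = 0.30)))  # 0.30 below band
  # zero-frequency alleles are ignored
  expect_true(call_heteroplasmy(c(A = 0.4, G = 0.6, C = 0)))
  expect_error(call_heteroplasmy(c(A = 0.9)), "two alleles")
  expect_error(call_heteroplasmy(c(A = 0.5, G = 0.4)), "sum")
})

test_that("profile TSV round trip is deterministic and position-sorted", {
  profs <- list(make_profile("b", c(5000, 300)), make_profile("a", 700))
  out <- withr::local_tempfile(fileext = ".tsv")
  tab <- write_variant_profiles(profs, out)
  expect_identical(tab$sample_id, c("a", "b", "b"))
  expect_identical(tab$position[2:3], c(300L, 5000L))
  reread <- utils::read.delim(out)
  expect_identical(nrow(reread), 3L)
})
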