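test_that("fragment manifests load with totals and reject malformed input", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrY\t0\t10\tA", "chrY\t10\t20\tA"), p)
  fr <- load_fragments(p)
  expect_equal(nrow(fr), 2)
  expect_equal(attr(fr, "total_bases"), 20L)

  empty <- withr::local_tempfile(fileext = ".bed")
  file.create(empty)
  fr0 <- load_fragments(empty)
  expect_equal(nrow(fr0), 0)
  expect_equal(attr(fr0, "total_bases"), 0L)

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrY\t0\t15\tA", "chrY\t10\t20\tA"), bad)
  expect_error(load_fragments(bad), "overlap")
  writeLines(c("chrY\t10\t20\tA", "chrY\t0\t5\tA"), bad)
  expect_error(load_fragments(bad), "sorted")
})

test_that("modern-call filtering applies FT, depth, blacklist and whitelist rules", {
  recs <- data.frame(
    sample_id = "s1",
    pos = c(100, 200, 300, 8417317, 19319427, 400),
    ref = "A", alt = "G",
    filter = c("PASS", "VQLow", "PASS", "PASS", "VQLow", "PASS"),
    ad_ref = 0L,
    ad_alt = c(3L, 10L, 2L, 30L, 1L, NA),
    stringsAsFactors = FALSE)
  expect_warning(kept <- filter_modern_calls(recs, filter_config()),
                 "allele depth")
  # PASS depth 3 kept; VQLow dropped; depth 2 dropped; blacklisted dropped
  # even at depth 30; whitelisted kept despite VQLow; NA depth dropped
  expect_setequal(kept$pos, c(100, 19319427))
})

test_that("filtering is idempotent", {
  recs <- data.frame(sample_id = "s1", pos = c(1, 2, 3) * 100,
                     ref = "C", alt = "T",
                     filter = c("PASS", "VQLow", "PASS"),
                     ad_ref = 0L, ad_alt = c(5L, 5L, 1L))
  cfg <- filter_config(site_blacklist = numeric(0), site_whitelist = numeric(0))
  once <- filter_modern_calls(recs, cfg)
  expect_identical(filter_modern_calls(once, cfg), once)
  anc <- data.frame(sample_id = "a", pos = c(10, 20), ref = "C", alt = "T",
                    filter = "PASS", ad_ref = c(2L, 3L), ad_alt = c(5L, 3L))
  once_a <- filter_ancient_calls(anc, cfg)
  expect_identical(filter_ancient_calls(once_a, cfg), once_a)
})

test_that("ancient-call rule requires alt depth strictly above ref depth", {
  cfg <- filter_config(site_blacklist = numeric(0), site_whitelist = numeric(0))
  recs <- data.frame(sample_id = "a", pos = c(10, 20, 30), ref = "A", alt = "T",
                     filter = "PASS",
                     ad_ref = c(2L, 2L, 10L), ad_alt = c(5L, 2L, 0L))
  expect_equal(filter_ancient_calls(recs, cfg)$pos, 10)
})

test_that("build_matrix restricts to fragments, fills reference, drops monomorphic", {
  frags <- data.frame(chrom = "chrY", start = c(0L, 100L), end = c(50L, 150L),
                      region = "A", effective_bases = 50L)
  ref <- paste(rep("A", 200), collapse = "")
  recs <- data.frame(sample_id = "s1", pos = 10L, ref = "A", alt = "G",
                     filter = "PASS", ad_ref = 0L, ad_alt = 9L)
  gm <- build_matrix(recs, frags, ref, samples = c("s1", "s2", "s3"))
  expect_equal(dim(gm$states), c(3, 1))
  expect_equal(unname(gm$states[, 1]), c("G", "A", "A"))

  outside <- transform(recs, pos = 75L)
  gm0 <- build_matrix(outside, frags, ref, samples = c("s1", "s2"))
  expect_equal(ncol(gm0$states), 0)

  confl <- rbind(recs, transform(recs, alt = "T"))
  expect_error(build_matrix(confl, frags, ref), "conflicting")
})

test_that("simulated VCF fixtures round-trip to the truth matrix", {
  for (seed in c(11, 23)) {
    truth <- if (seed == 11) mini_truth(11) else {
      cfg <- sim_config(layout = "mini", n_tips = 8,
                        ancient_tips = c(a1 = 30000), seed = seed)
      lay <- msymut:::mini_layout()
      set.seed(seed); ref <- simulate_reference(max(lay$bins$end) + 10)
      simulate_mutations(simulate_genealogy(cfg), lay, ref, cfg)
    }
    d <- withr::local_tempdir()
    emit_fixture(truth, d)
    frags <- load_fragments(file.path(d, "fragments.bed"))
    cfg0 <- filter_config(site_blacklist = numeric(0),
                          site_whitelist = numeric(0))
    anc <- names(truth$config$ancient_tips)
    recs <- do.call(rbind, lapply(rownames(truth$matrix$states), function(s) {
      r <- read_sample_vcf(file.path(d, paste0(s, ".vcf")), s)
      if (s %in% anc) filter_ancient_calls(r, cfg0)
      else filter_modern_calls(r, cfg0)
    }))
    gm <- build_matrix(recs, frags, truth$reference,
                       samples = rownames(truth$matrix$states))
    expect_identical(gm$states, truth$matrix$states)
    expect_identical(gm$positions, truth$matrix$positions)
  }
})
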