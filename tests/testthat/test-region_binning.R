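test_that("partition_fragments makes round(total/target) balanced bins per region", {
  frags <- data.frame(chrom = "chrY",
                      start = c(0, 40000, 80000, 120000),
                      end = c(40000, 80000, 120000, 160000),
                      region = "A",
                      effective_bases = 40000L)
  bins <- partition_fragments(frags, target_effective = 80000)
  expect_equal(nrow(bins), 2)
  expect_equal(bins$effective_bases, c(80000L, 80000L))

  small <- data.frame(chrom = "chrY", start = c(0, 5000), end = c(4000, 9275),
                      region = "B",
                      effective_bases = c(4000L, 4275L))
  b1 <- partition_fragments(small, target_effective = 80000)
  expect_equal(nrow(b1), 1)
  expect_equal(b1$effective_bases, 8275L)
})

test_that("partition matches exhaustive search over consecutive partitions", {
  exhaustive <- function(sizes, k) {
    n <- length(sizes); target <- sum(sizes) / k
    cuts <- utils::combn(n - 1, k - 1)
    best <- Inf
    for (j in seq_len(ncol(cuts))) {
      bounds <- c(0, cuts[, j], n)
      devs <- vapply(seq_len(k), function(g)
        abs(sum(sizes[(bounds[g] + 1):bounds[g + 1]]) - target), 0)
      best <- min(best, max(devs))
    }
    best
  }
  set.seed(4)
  for (rep in 1:20) {
    n <- sample(4:9, 1)
    sizes <- sample(100:5000, n)
    k <- sample(2:min(4, n), 1)
    grp <- msymut:::best_consecutive_partition(sizes, k)
    got <- max(abs(tapply(sizes, grp, sum) - sum(sizes) / k))
    expect_equal(got, exhaustive(sizes, k))
  }
})

test_that("base conservation holds for every partition", {
  set.seed(9)
  sizes <- sample(500:2000, 30)
  frags <- data.frame(chrom = "chrY",
                      start = cumsum(c(0, sizes[-30] + 5)),
                      region = rep(c("A", "B"), each = 15))
  frags$end <- frags$start + sizes
  frags$effective_bases <- sizes
  bins <- partition_fragments(frags, target_effective = 7000)
  expect_equal(sum(bins$effective_bases), sum(sizes))
})

test_that("published boundaries reproduce the 19 bins of the target region", {
  lay <- synthetic_fragments_from_bins(msy_bin_table(), compact = FALSE)
  bt <- msy_bin_table()
  bins <- bins_from_boundaries(lay$fragments, bt)
  expect_equal(nrow(bins), 19)
  expect_equal(sum(bins$n_fragments), 5274)
  expect_equal(sum(bins$effective_bases), 1495512)
  expect_equal(bins$effective_bases[bins$bin == 1], 91454)
  expect_equal(bins$effective_bases[bins$bin == 7], 78966)

  one <- data.frame(bin = 1L, region = "all",
                    initial_pos = 1L, final_pos = max(lay$fragments$end))
  expect_equal(bins_from_boundaries(lay$fragments, one)$n_fragments, 5274)

  split_mid <- data.frame(bin = 1:2, region = "A",
                          initial_pos = c(1L, lay$fragments$start[1] + 2L),
                          final_pos = c(lay$fragments$start[1] + 1L,
                                        max(lay$fragments$end)))
  expect_error(bins_from_boundaries(lay$fragments, split_mid), "straddles")
})

test_that("CpG position counting is context-correct and strand-symmetric", {
  frag <- data.frame(chrom = "c", start = 0L, end = 4L, region = "A",
                     effective_bases = 4L)
  expect_equal(count_cpg_positions(frag, "ACGT"), 2L)
  expect_equal(count_cpg_positions(frag, "CCCC"), 0L)
  expect_equal(count_cpg_positions(frag, "AGCA"), 0L)  # GC is not CpG
  expect_equal(count_cpg_positions(frag, "CGCG"), 4L)

  set.seed(2)
  s <- simulate_reference(500)
  frag <- data.frame(chrom = "c", start = 0L, end = 500L, region = "A",
                     effective_bases = 500L)
  revcomp <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(count_cpg_positions(frag, s), count_cpg_positions(frag, revcomp))
})

test_that("feature aggregation equals a per-base scan", {
  set.seed(7)
  frags <- data.frame(chrom = "c", start = c(10L, 50L), end = c(30L, 80L),
                      region = "A", effective_bases = c(20L, 30L))
  bin <- data.frame(bin = 1L, region = "A", start = 10L, end = 80L)
  track <- data.frame(start = sort(sample(0:90, 3)), end = 0L)
  track$end <- track$start + sample(5:20, 3)
  got <- aggregate_features(bin, frags, tracks = list(gene = track))
  base_in_track <- function(p) any(p >= track$start & p < track$end)
  per_base <- mean(vapply(c(10:29, 50:79), base_in_track, TRUE)) * 100
  expect_equal(got$gene_pct, per_base)

  full <- aggregate_features(bin, frags,
                             tracks = list(gene = data.frame(start = 0L, end = 100L)))
  expect_equal(full$gene_pct, 100)
  none <- aggregate_features(bin, frags,
                             tracks = list(gene = data.frame(start = 90L, end = 95L)))
  expect_equal(none$gene_pct, 0)

  sc <- data.frame(pos = c(15, 60, 85), score = c(1, 2, 9))
  expect_equal(aggregate_features(bin, frags,
                                  score_tracks = list(rt = sc))$rt_score, 1.5)
})
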