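test_that("Fitch event counts equal the exhaustive-labeling minimum", {
  set.seed(31)
  for (rep in 1:12) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n, rooted = TRUE, br = NULL)
    gm <- random_gm(n, 6, seed = 100 + rep)
    rownames(gm$states) <- tr$tip.label
    asg <- fitch_assign(tr, gm)
    for (s in seq_len(ncol(gm$states))) {
      expect_equal(asg$score[s],
                   oracle_fitch_site(tr, gm$states[, s]),
                   info = sprintf("rep %d site %d", rep, s))
    }
    expect_equal(nrow(asg$events), sum(asg$score))
    expect_equal(sum(asg$tree$edge.length), nrow(asg$events))
  }
})

test_that("fitch_score agrees with an independent parsimony implementation", {
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(5:12, 1)
    gm <- random_gm(n, 20, seed = rep)
    tr <- ape::rtree(n, rooted = FALSE, br = NULL)
    tr$tip.label <- rownames(gm$states)
    pd <- phangorn::phyDat(gm$states, type = "DNA")
    expect_equal(fitch_score(tr, gm),
                 as.integer(phangorn::parsimony(tr, pd)))
  }
})

test_that("single-tip derived alleles land on the terminal branch; shared ones recur", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  states <- matrix("A", 4, 2, dimnames = list(c("A", "B", "C", "D"), NULL))
  states["A", 1] <- "G"                 # private variant
  states[c("A", "C"), 2] <- "T"         # homoplasy on opposite clades
  gm <- make_gm(states, ref = c("A", "A"))
  asg <- fitch_assign(tr, gm)
  ev1 <- asg$events[asg$events$site == 1, ]
  expect_equal(nrow(ev1), 1)
  expect_equal(tr$edge[ev1$edge, 2], which(tr$tip.label == "A"))
  ev2 <- asg$events[asg$events$site == 2, ]
  expect_equal(nrow(ev2), 2)
  expect_equal(oracle_fitch_site(tr, states[, 2]), 2)
  expect_equal(asg$multi_hit$kind, "recurrent")
  expect_equal(asg$multi_hit$n_events, 2L)
})

test_that("hyper-recurrent detection flags >3 events but keeps double hits", {
  mh <- data.frame(pos = c(100L, 200L), n_events = c(4L, 2L),
                   kind = c("recurrent", "double_hit"))
  asg <- structure(list(multi_hit = mh), class = "fitch_assignment")
  expect_equal(detect_hyper_recurrent(asg), 100L)
  asg0 <- structure(list(multi_hit = mh[0, ]), class = "fitch_assignment")
  expect_equal(length(detect_hyper_recurrent(asg0)), 0)
})

test_that("rho equals brute-force path enumeration", {
  tr <- ape::read.tree(text = "(A:3,B:5);")
  ntip <- 2
  expect_equal(rho(tr, ntip + 1), 4)
  expect_equal(rho(tr, 1), 0)
  set.seed(17)
  for (rep in 1:5) {
    tr <- ape::rtree(sample(4:10, 1))
    tr$edge.length <- sample(0:8, nrow(tr$edge), replace = TRUE)
    r <- rho(tr)
    for (node in seq_along(r))
      expect_equal(r[node], oracle_rho(tr, node))
  }
})

test_that("perfect nested variants give the unique perfect phylogeny", {
  # nested derived sets: {A}, {A,B}, {A,B,C} on 4 haplotypes
  states <- rbind(A = c("G", "G", "G"), B = c("A", "G", "G"),
                  C = c("A", "A", "G"), D = c("A", "A", "A"))
  gm <- make_gm(states, ref = c("A", "A", "A"))
  tr <- build_parsimony_tree(gm, seed = 1)
  expect_equal(attr(tr, "parsimony_score"), 3L)
  rooted <- root_tree(tr, gm, outgroup = "D")
  asg <- fitch_assign(rooted, gm)
  expect_equal(nrow(asg$events), 3)
  expect_equal(nrow(asg$multi_hit), 0)
})

test_that("tree search attains the exhaustive-topology optimum on small matrices", {
  for (seed in c(3, 8)) {
    n <- 6
    gm <- random_gm(n, 10, seed = seed)
    tr <- build_parsimony_tree(gm, seed = 1)
    all_tops <- phangorn::allTrees(n, rooted = FALSE,
                                   tip.label = rownames(gm$states))
    pd <- phangorn::phyDat(gm$states, type = "DNA")
    best <- min(vapply(all_tops, function(t)
      as.integer(phangorn::parsimony(t, pd)), 0L))
    expect_equal(attr(tr, "parsimony_score"), best)
  }
})

test_that("simulated 30-tip topologies are recovered (zero-event branches collapsed)", {
  cfg <- sim_config(layout = "mini", n_tips = 30, ancient_tips = numeric(0),
                    cpg_factor = 1, base_rate = 3e-9, seed = 21)
  lay <- msymut:::mini_layout()
  set.seed(21); ref <- simulate_reference(max(lay$bins$end) + 10)
  tr <- simulate_genealogy(cfg)
  truth <- simulate_mutations(tr, lay, ref, cfg)
  # drop multi-hit positions so the signal is recurrence-free
  multi <- names(which(table(truth$events$pos) > 1))
  gm <- truth$matrix
  keep <- !(colnames(gm$states) %in% multi)
  gm$states <- gm$states[, keep, drop = FALSE]
  gm$positions <- gm$positions[keep]; gm$ref <- gm$ref[keep]
  inferred <- build_parsimony_tree(gm, seed = 2)
  true_collapsed <- ape::di2multi(ape::unroot(truth$tree), tol = 0.5)
  inf_asg <- fitch_assign(ape::root(inferred, inferred$tip.label[1],
                                    resolve.root = TRUE), gm)
  inf_collapsed <- ape::di2multi(ape::unroot(inf_asg$tree), tol = 0.5)
  expect_equal(phangorn::RF.dist(true_collapsed, inf_collapsed), 0)
})

test_that("branch sectioning follows event counts, rho and node ages", {
  # chain tree: ((A:2,B:4):30,(C:12,D:40):5);  counts as edge lengths
  tr <- ape::read.tree(text = "((A:2,B:4):30,(C:12,D:40):5);")
  ntip <- 4
  ages <- c(0, 0, 0, 0, 100000, 20000, 80000)  # tips, root, AB node, CD node
  cfg <- section_config(deep_min_age = 68000)
  lab <- section_branches(tr, cfg, node_ages = ages)
  child <- tr$edge[, 2]
  # terminal branches with <= 10 events are very recent
  expect_equal(lab[child == which(tr$tip.label == "A")], "very_recent")
  expect_equal(lab[child == which(tr$tip.label == "B")], "very_recent")
  # C (12 events, parent rho = 26 > 20) is not recent; D likewise
  # CD node age 80 ky >= 68 ky -> its subtending branch is deep
  expect_equal(lab[child == 7], "deep")
  # rho at AB node = 3 <= 20 -> terminal C? no; A,B already very_recent;
  # branch to AB node: child age 20 ky < 68 ky, parent's rho large -> intermediate
  expect_equal(lab[child == 6], "intermediate")
  expect_error(section_branches(tr, cfg), "dated")

  # boundary: terminal branch of exactly 10 events is very recent;
  # node with rho exactly 20 makes its subtending branches recent
  tr2 <- ape::read.tree(text = "((A:10,B:30):40,C:100);")
  ages2 <- c(0, 0, 0, 50000, 10000)
  lab2 <- section_branches(tr2, section_config(), node_ages = ages2)
  expect_equal(lab2[tr2$edge[, 2] == 1], "very_recent")
  expect_equal(rho(tr2, 5), 20)
  expect_equal(lab2[tr2$edge[, 2] == 2], "recent")  # parent rho 20, 30 events
})

test_that("excluded clades stay unlabeled in sectioning", {
  tr <- ape::read.tree(text = "((A:2,B:4):30,(C:12,D:40):5);")
  ages <- c(0, 0, 0, 0, 100000, 20000, 80000)
  lab <- section_branches(tr, section_config(excluded_tips = c("C", "D")),
                          node_ages = ages)
  expect_true(all(is.na(lab[tr$edge[, 2] %in% c(3, 4, 7)])))
})

test_that("clades extract by defining site or tip set, including nested requests", {
  truth <- mini_truth()
  rooted <- truth$dated_tree
  asg <- fitch_assign(rooted, truth$matrix)
  # pick a private event (one per position) on an internal edge if any
  single <- asg$events[!asg$events$pos %in% asg$multi_hit$pos, ]
  ev <- single[1, ]
  cl <- extract_clade(rooted, asg, defining_site = ev$pos)
  expect_true(all(cl$tips %in% rooted$tip.label))
  expect_equal(cl$edge, ev$edge)
  # MRCA request and a nested sub-request both resolve
  two <- rooted$tip.label[1:2]
  cl2 <- extract_clade(rooted, tips = two)
  expect_true(all(two %in% cl2$tips))
  cl3 <- extract_clade(rooted, tips = cl2$tips[1])
  expect_equal(cl3$tips, cl2$tips[1])
})

test_that("removing a clade removes exactly its assigned events", {
  truth <- mini_truth()
  asg <- fitch_assign(truth$dated_tree, truth$matrix)
  tr <- asg$tree
  node <- tr$edge[which(tr$edge[, 2] > length(tr$tip.label))[1], 2]
  sub_edges <- which(tr$edge[, 2] %in% msymut:::descendant_nodes(tr, node))
  inside <- sum(asg$events$edge %in% sub_edges)
  expect_equal(sum(tr$edge.length[sub_edges]), inside)
  expect_equal(sum(tr$edge.length), nrow(asg$events))
})
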