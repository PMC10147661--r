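# Genotype-network statistics against brute-force oracles on toy maps.

test_that("lazy labeling caches and closed maps refuse unlabeled genotypes", {
  calls <- 0
  rule <- function(g) {
    calls <<- calls + 1
    "BLUE"
  }
  map <- phenotype_map(rule = rule)
  g <- "1-2-0-4-0-0|PH-PM"
  map_label(map, c(g, g))
  map_label(map, g)
  expect_equal(calls, 1)
  closed <- phenotype_map(labels = c(`1-2-0-4-0-0|PH-PM` = "NF"))
  expect_equal(map_label(closed, g), "NF")
  expect_error(map_label(closed, "1-2-0-4-0-5|PH-PM"), "closed")
})

test_that("connected components equal the union-find oracle", {
  toy <- make_toy_phenotype_map(80, rule_hash(probs = c(NF = 0.5, BLUE = 0.3, GREEN = 0.2)),
                                seed = 21)
  got <- map_components(toy$map, toy$genotypes)
  want <- oracle_components(toy$genotypes, map_label(toy$map, toy$genotypes))
  # same partition: identical multiset of sorted component member lists
  got_sets <- sort(vapply(split(got$genotype, paste(got$label, got$component)),
                          function(v) paste(sort(v), collapse = ";"), character(1)))
  want_sets <- sort(vapply(want, function(v) paste(sort(v), collapse = ";"), character(1)))
  expect_equal(unname(got_sets), unname(want_sets))
  # two same-label genotypes at distance 2, joined only through an NF
  # intermediate, form two components
  labs <- c("BLUE", "NF", "BLUE")
  chain <- c("1-2-0-4-0-0|PH-PH", "1-2-0-4-0-0|PM-PH", "1-2-0-4-0-0|PM-PM")
  m2 <- phenotype_map(labels = setNames(labs, chain))
  comp <- map_components(m2, chain, phenotype = "BLUE")
  expect_equal(length(unique(comp$component)), 2)
})

test_that("evolvability and robustness match direct neighbor counts", {
  toy <- make_toy_phenotype_map(40, rule_hash(probs = c(NF = 0.6, BLUE = 0.4)),
                                seed = 5)
  for (g in toy$genotypes[1:12]) {
    nb <- oracle_neighbors(g)
    labs <- map_label(toy$map, nb)
    expect_equal(genotype_evolvability(g, toy$map), length(unique(labs)))
    expect_equal(genotype_robustness(g, toy$map),
                 mean(labs == map_label(toy$map, g)))
    # robustness 1 iff evolvability 1 (on maps where own label appears among
    # neighbors this is the exact equivalence)
    if (genotype_robustness(g, toy$map) == 1) {
      expect_equal(genotype_evolvability(g, toy$map), 1)
    }
  }
  # constant map: robustness 1, evolvability 1 everywhere
  cm <- phenotype_map(rule = rule_constant("BLUE"))
  expect_equal(genotype_robustness(toy$genotypes[1], cm), 1)
  expect_equal(genotype_evolvability(toy$genotypes[1], cm), 1)
})

test_that("per-slot robustness isolates the perturbed coordinate", {
  # labels ignore promoters entirely: slots 7-8 perfectly robust
  edge_rule <- function(g) if (substr(g, 1, 1) == "0") "NF" else "BLUE"
  m <- phenotype_map(rule = edge_rule)
  set.seed(3)
  gs <- sample_genotypes(6)
  rp <- robustness_per_perturbation(m, gs, slots = 7:8)
  expect_true(all(rp$robustness == 1))
  # labels keyed to the promoter-B slot: slot 7 changes are maximally
  # disruptive at the rule's boundary
  mB <- phenotype_map(rule = rule_by_promoter_B())
  g_b1 <- "1-2-0-4-0-0|PH-PM" # promoter level 1
  rpB <- robustness_per_perturbation(mB, g_b1, slots = 7)
  expect_equal(rpB$robustness, 1 / 3) # of PM, PL, ZERO only PM keeps BLUE
  rp8 <- robustness_per_perturbation(mB, g_b1, slots = 8)
  expect_equal(rp8$robustness, 1) # promoter C never enters the rule
  expect_true(all(stats::na.omit(rp$robustness) >= 0 &
                    stats::na.omit(rp$robustness) <= 1))
})

test_that("transition frequencies match the brute-force oracle and sum to one", {
  toy <- make_toy_phenotype_map(50, rule_hash(probs = c(NF = 0.4, BLUE = 0.3, GREEN = 0.3)),
                                seed = 9)
  gs <- toy$genotypes[1:15]
  tf <- transition_frequencies(toy$map, gs)
  phenos <- toy$map$phenotypes
  # per-genotype neighbor label fractions, recomputed independently
  fr <- t(vapply(gs, function(g) {
    labs <- map_label(toy$map, oracle_neighbors(g))
    vapply(phenos, function(p) mean(labs == p), numeric(1))
  }, numeric(3)))
  expect_equal(unname(rowSums(fr)), rep(1, length(gs)))
  src <- map_label(toy$map, gs)
  for (r in seq_len(nrow(tf))) {
    v <- fr[src == tf$source[r], match(tf$target[r], phenos)]
    if (!length(v)) {
      expect_true(is.na(tf$median[r]))
    } else {
      expect_equal(tf$median[r], median(v))
      expect_equal(tf$q25[r], quantile(v, 0.25, names = FALSE))
    }
  }
  # the diagonal median is the median robustness of that phenotype
  for (p in unique(src)) {
    rob <- vapply(gs[src == p], genotype_robustness, numeric(1), map = toy$map)
    expect_equal(tf$median[tf$source == p & tf$target == p], median(rob))
  }
  # homogeneous map: diagonal 1, off-diagonal 0
  hm <- phenotype_map(rule = rule_constant("NF"))
  tfh <- transition_frequencies(hm, gs[1:3])
  expect_equal(tfh$median[tfh$source == "NF" & tfh$target == "NF"], 1)
  expect_equal(tfh$median[tfh$source == "NF" & tfh$target == "BLUE"], 0)
})

test_that("topology summary averages match a direct computation and cluster sanely", {
  toy <- make_toy_phenotype_map(60, rule_hash(probs = c(NF = 0.5, BLUE = 0.5)), seed = 2)
  gs <- toy$genotypes[1:20]
  ts <- topology_summary(toy$map, gs, k = 3)
  for (r in seq_len(nrow(ts))) {
    members <- gs[vapply(gs, topology_of, character(1)) == ts$topology[r]]
    E_direct <- mean(vapply(members, function(g) {
      length(unique(map_label(toy$map, oracle_neighbors(g))))
    }, numeric(1)))
    expect_equal(ts$E[r], E_direct)
    EF_direct <- mean(vapply(members, function(g) {
      nb <- oracle_neighbors(g)
      fixed <- vapply(nb, function(h) topology_of(h) == ts$topology[r], logical(1))
      length(unique(map_label(toy$map, nb[fixed])))
    }, numeric(1)))
    expect_equal(ts$E_F[r], EF_direct)
  }
  expect_true(all(ts$E >= 1 & ts$E <= 2 + 1e-12))
  expect_true(all(ts$R >= 0 & ts$R <= 1))
  expect_lte(length(unique(ts$cluster)), 3)
  # an always-NF map has evolvability exactly one everywhere
  nf <- phenotype_map(rule = rule_constant("NF"))
  ts_nf <- topology_summary(nf, gs, k = 2)
  expect_true(all(ts_nf$E == 1 & ts_nf$E_F == 1))
})

test_that("random walk lengths follow the exact absorption distribution", {
  # label = promoter-B level <= 2; exactly 2 of each genotype's neighbors
  # change the label, so absorption depends only on the edge count
  mB <- phenotype_map(rule = rule_by_promoter_B())
  start <- "1-2-0-4-0-0|PH-PM" # 3 edges
  set.seed(99)
  rw <- random_walk_lengths(mB, rep(start, 400), max_steps = 120)
  exact <- oracle_walk_distribution(E0 = 3, kmax = 120)
  med_exact <- oracle_distribution_median(exact)
  expect_lte(abs(attr(rw, "median") - med_exact), 2)
  expect_true(all(rw$length >= 1 & rw$length <= 120))
  # degenerate maps: immediate change vs never
  unique_rule <- function(g) g
  expect_true(all(random_walk_lengths(phenotype_map(rule = unique_rule),
                                      rep(start, 5), max_steps = 10)$length == 1))
  hm <- random_walk_lengths(phenotype_map(rule = rule_constant("NF")),
                            rep(start, 5), max_steps = 7)
  expect_true(all(hm$censored))
  expect_equal(attr(hm, "median"), 7)
})

test_that("epistasis prevalence matches exhaustive pair enumeration", {
  toy <- make_toy_phenotype_map(30, rule_hash(probs = c(NF = 0.5, BLUE = 0.5)), seed = 14)
  rule_lab <- function(g) map_label(toy$map, g)
  for (g0 in toy$genotypes[1:3]) {
    got <- epistasis_prevalence(toy$map, g0)
    # oracle: enumerate all ordered-change pairs through string surgery
    mu <- grnmap:::genotype_mutations(g0)
    phi <- rule_lab(g0)
    pairs <- 0
    inst <- 0
    for (i in seq_len(nrow(mu) - 1)) {
      for (j in (i + 1):nrow(mu)) {
        if (mu$slot[i] == mu$slot[j]) next
        dbl <- grnmap:::apply_two_changes(as_genotype(g0), mu$genotype[i], mu$slot[i],
                                          mu$genotype[j], mu$slot[j], parts_library())
        if (is.null(dbl)) next
        pairs <- pairs + 1
        if (rule_lab(dbl) == phi &&
            sum(rule_lab(mu$genotype[i]) == phi, rule_lab(mu$genotype[j]) == phi) == 1) {
          inst <- inst + 1
        }
      }
    }
    expect_equal(got$pairs, pairs)
    expect_equal(got$instances, inst)
    expect_equal(got$prevalence, inst / pairs)
  }
  # homogeneous map: zero prevalence
  hm <- epistasis_prevalence(phenotype_map(rule = rule_constant("NF")),
                             toy$genotypes[1], max_pairs = 200)
  expect_equal(hm$prevalence, 0)
  # a single off-phenotype intermediate yields exactly the pairs through it
  g <- "1-2-0-4-0-0|PH-PM"
  bad <- "1-2-0-4-0-0|PM-PM" # the slot-7 change to PM
  one_off <- function(x) if (x == bad) "NF" else "BLUE"
  mo <- phenotype_map(rule = one_off)
  eo <- epistasis_prevalence(mo, g)
  mu <- grnmap:::genotype_mutations(g)
  # every valid pair containing the bad intermediate is epistatic
  n_with_bad <- sum(vapply(which(mu$genotype == bad), function(i) {
    sum(vapply(seq_len(nrow(mu)), function(j) {
      mu$slot[j] != mu$slot[i] &&
        !is.null(grnmap:::apply_two_changes(as_genotype(g), mu$genotype[i], mu$slot[i],
                                            mu$genotype[j], mu$slot[j], parts_library()))
    }, logical(1)))
  }, numeric(1)))
  expect_equal(eo$instances, n_with_bad)
})

test_that("stratified sampling and caching are reproducible under a fixed seed", {
  rule <- rule_hash(probs = c(NF = 0.7, BLUE = 0.3), seed = 4)
  m1 <- phenotype_map(rule = rule)
  set.seed(123)
  s1 <- sample_phenotype_strata(m1, c(NF = 10, BLUE = 5))
  m2 <- phenotype_map(rule = rule)
  set.seed(123)
  s2 <- sample_phenotype_strata(m2, c(NF = 10, BLUE = 5))
  expect_identical(s1, s2)
  expect_equal(sum(s1$label == "NF"), 10)
  expect_equal(sum(s1$label == "BLUE"), 5)
})
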