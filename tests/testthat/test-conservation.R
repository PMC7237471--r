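test_that("proteome preprocessing enforces length and start-methionine rules", {
  rec <- data.frame(
    id = c("short_met", "long_nomet", "ok", "short_nomet"),
    species = "Ath",
    sequence = c(paste0("M", strrep("A", 98)),      # 99 aa, starts M
                 paste0("K", strrep("A", 149)),     # 150 aa, no M
                 paste0("M", strrep("A", 149)),     # 150 aa, starts M
                 "KAV"),
    stringsAsFactors = FALSE)
  rec$length <- nchar(rec$sequence)
  kept <- preprocess_proteome(rec)
  expect_equal(kept$id, "ok")
  rep <- attr(kept, "removal_report")
  expect_equal(unname(rep[c("too_short", "no_start_met", "both", "kept")]),
               c(1, 1, 1, 1))
})

test_that("preprocessing retains exactly the known-clean fraction of a synthetic proteome", {
  set.seed(301)
  n <- 500
  clean <- runif(n) > 0.12
  seqs <- vapply(seq_len(n), function(i) {
    len <- if (clean[i]) sample(100:300, 1) else sample(20:99, 1)
    s <- random_protein(len)
    if (!clean[i] && runif(1) < 0.5) s <- paste0("K", substr(s, 2, len))
    s
  }, character(1))
  rec <- data.frame(id = sprintf("p%03d", 1:n), species = "Syn",
                    sequence = seqs, length = nchar(seqs),
                    stringsAsFactors = FALSE)
  expect_equal(nrow(preprocess_proteome(rec)), sum(clean))
})

test_that("2-of-2 consensus equals the corresponding workflow and demands both calls", {
  calls <- call_table(data.frame(
    protein = rep(c("p1", "p2", "p3"), 2),
    predictor = rep(c("TargetP", "Localizer"), each = 3),
    plastid = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)))
  flags <- consensus_targeting(calls)
  expect_equal(flags, c(p1 = TRUE, p2 = FALSE, p3 = FALSE))
  expect_error(consensus_targeting(calls[, "TargetP", drop = FALSE]), "Localizer")

  set.seed(303)
  m <- matrix(runif(400) < 0.5, 200, 2,
              dimnames = list(sprintf("q%03d", 1:200), c("TargetP", "Localizer")))
  expect_identical(consensus_targeting(m),
                   apply_workflow(c("TargetP", "Localizer"), 2, m))
})

test_that("species profiles tally members exactly", {
  sp <- c(a = "Ath", b = "Ath", c = "Osa")
  prof <- build_profile(c("a", "b", "c"), sp, plastid_set = c("a", "c"))
  expect_equal(sum(prof$n_plastid) + sum(prof$n_other), 3)
  expect_equal(prof$n_plastid[prof$species == "Ath"], 1L)
  expect_equal(prof$n_other[prof$species == "Osa"], 0L)
  expect_error(build_profile(c("a", "zz"), sp, "a"), "zz")

  set.seed(307)
  members <- sprintf("m%02d", 1:50)
  sp2 <- setNames(sample(c("Ath", "Osa", "Sly"), 50, replace = TRUE), members)
  plastid <- sample(members, 20)
  prof2 <- build_profile(members, sp2, plastid)
  for (s in prof2$species) {
    expect_equal(prof2$n_plastid[prof2$species == s],
                 sum(members %in% plastid & sp2 == s))
  }
})

test_that("category rules follow the conserved / semi-conserved / NPTP definitions", {
  tax <- default_taxonomy()
  all_sp <- tax$species$species
  # every species with a plastid member -> conserved
  p1 <- data.frame(species = all_sp, n_plastid = 1L, n_other = 0L)
  expect_equal(classify_cluster(p1, tax)$category, "conserved")
  # one species rescued by the >= 4 non-plastid exemption
  p2 <- p1
  p2$n_plastid[1] <- 0L
  p2$n_other[1] <- 5L
  expect_equal(classify_cluster(p2, tax)$category, "conserved")
  # three non-plastid members are not enough to rescue
  p2$n_other[1] <- 3L
  expect_false(classify_cluster(p2, tax)$category == "conserved")
  # four species, plastid only in one -> NPTP
  p3 <- data.frame(species = c("Osa", "Bdi", "Ath", "Sly"),
                   n_plastid = c(2L, 0L, 0L, 0L), n_other = c(0L, 1L, 1L, 1L))
  cls3 <- classify_cluster(p3, tax)
  expect_equal(cls3$category, "nptp")
  expect_equal(cls3$group, "Osa")
  # plastid in three monocots, eudicots with single non-plastid members
  p4 <- data.frame(species = c("Osa", "Bdi", "Aam", "Ath", "Sly"),
                   n_plastid = c(1L, 2L, 1L, 0L, 0L), n_other = c(0L, 0L, 0L, 1L, 1L))
  cls4 <- classify_cluster(p4, tax)
  expect_equal(cls4$category, "semi_conserved")
  expect_equal(cls4$group, "monocot")
  # confined to Poaceae: the smallest qualifying group wins
  p5 <- data.frame(species = c("Osa", "Bdi", "Ath"),
                   n_plastid = c(1L, 1L, 0L), n_other = c(0L, 0L, 1L))
  expect_equal(classify_cluster(p5, tax)$group, "Poaceae")
  # an outside species with >= 4 non-plastid members disqualifies the clade
  p6 <- p4
  p6$n_other[p6$species == "Ath"] <- 4L
  expect_equal(classify_cluster(p6, tax)$category, "unclassified")
  # outgroup-specific targeting needs two plastid sequences
  p7 <- data.frame(species = c("Atr", "Osa", "Ath"),
                   n_plastid = c(2L, 0L, 0L), n_other = c(0L, 1L, 1L))
  expect_equal(classify_cluster(p7, tax)$category, "semi_conserved")
  p7$n_plastid[1] <- 1L
  expect_equal(classify_cluster(p7, tax)$category, "nptp")
  # single-species clusters are discarded
  p8 <- data.frame(species = "Ath", n_plastid = 3L, n_other = 2L)
  expect_equal(classify_cluster(p8, tax)$category, "discarded_single_species")
})

test_that("classification agrees with an independent rule evaluator on random profiles", {
  tax <- default_taxonomy()
  set.seed(311)
  params <- classification_params()
  profs <- replicate(10000, rand_profile(tax), simplify = FALSE)
  categories <- vapply(profs, function(p) classify_cluster(p, tax, params)$category,
                       character(1))
  want <- vapply(profs, oracle_classify, character(1), tax = tax, params = params)
  expect_identical(categories, want)
  # categories are mutually exclusive and exhaustive by construction;
  # check the sweep actually exercised them all
  expect_setequal(unique(categories),
                  c("conserved", "semi_conserved", "nptp", "unclassified",
                    "discarded_single_species"))
})

test_that("the exemption count moves conserved and semi-conserved in opposite directions", {
  tax <- default_taxonomy()
  set.seed(313)
  profs <- replicate(300, rand_profile(tax), simplify = FALSE)
  count_cat <- function(k) {
    cats <- vapply(profs, function(p) {
      classify_cluster(p, tax, classification_params(fn_exemption = k))$category
    }, character(1))
    table(factor(cats, levels = c("conserved", "semi_conserved", "nptp",
                                  "unclassified", "discarded_single_species")))
  }
  counts <- lapply(2:6, count_cat)
  conserved <- vapply(counts, `[[`, numeric(1), "conserved")
  semi <- vapply(counts, `[[`, numeric(1), "semi_conserved")
  expect_true(all(diff(conserved) <= 0))  # stricter species qualification
  expect_true(all(diff(semi) >= 0))       # weaker outside-clade disqualifier
})

test_that("classify_all recovers scenarios exactly under perfect calls", {
  mix <- c(conserved = 0.25, clade_specific = 0.25, species_unique = 0.25,
           non_plastid = 0.25)
  co <- simulate_corpus(n_families = 60, scenario_mix = mix, seed = 317)
  calls <- simulate_calls(co$truth, data.frame(name = c("TargetP", "Localizer"),
                                               se = 1, fpr = 0), seed = 318)
  flags <- consensus_targeting(calls)
  res <- classify_all(split(co$truth$id, co$truth$family),
                      names(flags)[flags], species_lookup(co$records),
                      default_taxonomy())
  map <- c(conserved = "conserved", clade_specific = "semi_conserved",
           species_unique = "nptp", non_plastid = "unclassified")
  want <- unname(map[co$families$scenario[match(res$classification$cluster,
                                                co$families$family)]])
  expect_identical(res$classification$category, want)
  # clade-specific families carry their generating clade
  semi <- res$classification[res$classification$category == "semi_conserved", ]
  gen <- co$families[match(semi$cluster, co$families$family), ]
  expect_identical(semi$group, gen$group)
})

test_that("the per-species summary counts NPTPs and unique targeting correctly", {
  tax <- default_taxonomy()
  sp <- c(a1 = "Osa", a2 = "Ath", a3 = "Sly",
          b1 = "Osa", b2 = "Bdi", b3 = "Ath",
          c1 = "Ath")
  part <- list(F1 = c("a1", "a2", "a3"), F2 = c("b1", "b2", "b3"), F3 = "c1")
  res <- classify_all(part, plastid_set = c("a1", "b1", "b2"), sp, tax)
  by <- res$by_species
  expect_equal(by$nptp[by$species == "Osa"], 1L)
  expect_equal(by$nptp[by$species == "Ath"], 0L)
  expect_equal(by$unique_plastid[by$species == "Osa"], 1L)
  expect_equal(by$total_clusters[by$species == "Ath"], 3L)
  expect_equal(by$single_species_clusters[by$species == "Ath"], 1L)
})

test_that("an empty cluster set yields empty tables", {
  res <- classify_all(list(), character(0), character(0), default_taxonomy())
  expect_equal(nrow(res$classification), 0L)
})
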