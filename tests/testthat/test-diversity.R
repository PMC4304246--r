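test_that("rank-1 conventions and the hand-walked example hold exactly", {
  # rank 1: A(p1) = {a,b}, A_rel = {a}
  ann <- list(p1 = c("a", "b"))
  f <- extract_diversity_features("p1", ann, a_rel = "a")
  expect_equal(unname(f["p1", ]), c(1, 1, 1, 0, 0, 0, 0))

  # ranks p1={a}, p2={a,b}, p3={b,c}, A_rel={a,b}: features at rank 3
  ann <- list(p1 = "a", p2 = c("a", "b"), p3 = c("b", "c"))
  f <- extract_diversity_features(c("p1", "p2", "p3"), ann, a_rel = c("a", "b"))
  expect_equal(unname(f["p3", ]), c(1, 1, 0, 1, 1, 1, 1))
})

test_that("unannotated ranked passages are rejected with their ids", {
  expect_error(extract_diversity_features(c("p1", "p9"), list(p1 = "a")), "p9")
})

test_that("per-rank identities hold on random ranking/annotation instances", {
  withr::with_seed(81, {
    for (rep in 1:200) {
      inst <- random_aspect_instance()
      f <- extract_diversity_features(inst$pids, inst$ann, inst$a_rel)
      sizes <- lengths(lapply(inst$ann[inst$pids], unique))
      expect_equal(f[, "NewRelAsp"] + f[, "OldRelAsp"], f[, "RelAsp"])
      expect_equal(unname(f[, "RelAsp"] + f[, "NonRelAsp"]), unname(sizes))
      ratios <- f[, c("NewAspPsg", "PctRelAsp", "PctUniqRelAsp")]
      expect_true(all(ratios >= 0 & ratios <= 1))
      # summing NewRelAsp over ranks counts the covered relevant aspects
      expect_equal(sum(f[, "NewRelAsp"]),
                   length(intersect(unique(unlist(inst$ann)), inst$a_rel)))
    }
  })
})

test_that("moving a passage later never increases its NewRelAsp", {
  withr::with_seed(82, {
    for (rep in 1:30) {
      inst <- random_aspect_instance(n = 8)
      f1 <- extract_diversity_features(inst$pids, inst$ann, inst$a_rel)
      i <- sample(1:7, 1)
      perm <- append(inst$pids[-i], inst$pids[i], after = sample(i:7, 1))
      f2 <- extract_diversity_features(perm, inst$ann, inst$a_rel)
      expect_lte(f2[inst$pids[i], "NewRelAsp"], f1[inst$pids[i], "NewRelAsp"])
    }
  })
})

test_that("the 15-column training matrix keeps the documented schema", {
  withr::with_seed(83, {
    gen <- matrix(stats::rnorm(24), 3, 8,
                  dimnames = list(c("p1", "p2", "p3"), general_feature_names()))
    ann <- list(p1 = "a", p2 = character(), p3 = c("a", "b"))
    div <- extract_diversity_features(c("p2", "p1", "p3"), ann, "a")
    ext <- build_diversity_training_set(gen, div)
    expect_identical(colnames(ext),
                     c(general_feature_names(), diversity_feature_names()))
    expect_identical(rownames(ext), rownames(gen))
    expect_equal(ext[, 1:8], gen)
    expect_equal(ext["p3", "RelAsp"], div["p3", "RelAsp"])
    # disjoint keys are an error
    bad <- div; rownames(bad) <- c("x1", "x2", "x3")
    expect_error(build_diversity_training_set(gen, bad), "different")
  })
})

test_that("zero diversity weights rank identically to the general model", {
  withr::with_seed(84, {
    gen <- matrix(stats::rnorm(40), 5, 8,
                  dimnames = list(sprintf("p%d", 1:5), general_feature_names()))
    ann <- stats::setNames(rep(list("a"), 5), sprintf("p%d", 1:5))
    div <- extract_diversity_features(sprintf("p%d", 1:5), ann, "a")
    ext <- build_diversity_training_set(gen, div)
    w8 <- stats::setNames(stats::rnorm(8), general_feature_names())
    w15 <- c(w8, stats::setNames(numeric(7), diversity_feature_names()))
    expect_equal(rank_passages(linear_model(w8), gen)$passage_id,
                 rank_passages(linear_model(w15), ext)$passage_id)
  })
})

test_that("score combination is the stated convex mixture with validation", {
  expect_equal(combine_scores(0.2, 0.8, combine_config(0.5)), 0.5)
  expect_equal(combine_scores(c(1, 0), c(0, 1), 0.3), c(0.3, 0.7))
  expect_error(combine_config(1.2), "alpha")
  expect_error(combine_config(-0.1), "alpha")
  cfg <- combine_config(0.35)
  expect_identical(cfg$beta, 1 - 0.35)
  expect_equal(combine_config()$alpha, 0.7)
})

test_that("alpha boundaries reproduce the constituent rankings item for item", {
  withr::with_seed(85, {
    for (rep in 1:10) {
      pids <- sprintf("p%02d", 1:12)
      g <- divrank:::ranked_list(pids, stats::rnorm(12))
      d <- divrank:::ranked_list(pids, stats::rnorm(12))
      expect_identical(combine_rankings(g, d, 1)$passage_id, g$passage_id)
      expect_identical(combine_rankings(g, d, 0)$passage_id, d$passage_id)
    }
    # degenerate constant scores fall back to the id tie rule on both sides
    g <- divrank:::ranked_list(c("pb", "pa"), c(1, 1))
    d <- divrank:::ranked_list(c("pa", "pb"), c(2, 1))
    expect_identical(combine_rankings(g, d, 1)$passage_id, g$passage_id)
  })
})

test_that("alpha sweep is recomputable per point and rejects an empty grid", {
  sc <- synth_config(num_queries = 8, passages_per_query = 15,
                     vocab_size = 300, seed = 9)
  ds <- build_ltr_dataset(generate_corpus(sc))
  cfg <- train_config(seed = 9, restarts = 2)
  curve <- sweep_alpha(ds, grid = c(0.2, 0.5, 0.8), cfg = cfg)
  expect_equal(nrow(curve), 3L)
  expect_true(all(curve$aspect_map >= 0 & curve$aspect_map <= 1))
  # a single-point sweep reproduces the corresponding row
  single <- sweep_alpha(ds, grid = 0.5, cfg = cfg)
  expect_equal(single[1, -1], curve[curve$alpha == 0.5, -1], ignore_attr = TRUE)
  # deterministic under the fixed seed
  expect_equal(sweep_alpha(ds, grid = c(0.2, 0.5, 0.8), cfg = cfg), curve)
  expect_error(sweep_alpha(ds, grid = numeric(), cfg = cfg), "empty")
})

test_that("an alpha=1 sweep reproduces the general model's metrics exactly", {
  sc <- synth_config(num_queries = 6, passages_per_query = 12,
                     vocab_size = 300, seed = 10)
  ds <- build_ltr_dataset(generate_corpus(sc))
  cfg <- train_config(seed = 10, restarts = 2)
  curve <- sweep_alpha(ds, grid = 1.0, cfg = cfg)
  # recompute gLTR-only metrics with the same folds
  sp <- divrank:::split_queries(names(ds$queries), cfg$seed)
  folds <- list(list(train = sp$a, test = sp$b), list(train = sp$b, test = sp$a))
  fold_metrics <- lapply(folds, function(f) {
    model <- train_combined(ds, f$train, cfg)
    rankings <- lapply(ds$queries[f$test], function(q)
      rank_passages(model$general, q$features))
    names(rankings) <- f$test
    divrank:::evaluate_rankings(rankings, ds)
  })
  expect_equal(unlist(curve[1, -1]),
               (fold_metrics[[1]] + fold_metrics[[2]]) / 2,
               ignore_attr = TRUE)
})
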