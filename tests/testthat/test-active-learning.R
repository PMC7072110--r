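test_that("cosine similarity matches direct arithmetic", {
  expect_equal(cosine_similarity(c(3, 4), c(3, 4)), 1.0)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0.0)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), 1 / sqrt(2), tolerance = 1e-9)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), class = "handbaa_degenerate_error")
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)), class = "handbaa_contract_error")
})

test_that("disagreement equals the brute-force mean over member pairs", {
  img <- matrix(0, 2, 2)
  # hand-computed case: pairwise sims {0, 0, 1} -> mean 1/3
  com <- stub_committee(list(c(1, 0), c(0, 1), c(1, 0)))
  expect_equal(disagreement_score(com, img), 1 / 3, tolerance = 1e-12)
  expect_equal(disagreement_score(com, img, aggregate = "min"), 0)
  # identical members give a score of exactly 1
  same <- stub_committee(list(c(2, 1), c(2, 1)))
  expect_equal(disagreement_score(same, img), 1.0)
  set.seed(13)
  for (k in c(2, 3, 5)) {
    vecs <- lapply(seq_len(k), function(i) rnorm(6))
    com <- stub_committee(vecs)
    acc <- c()
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      acc <- c(acc, sum(vecs[[i]] * vecs[[j]]) /
                 (sqrt(sum(vecs[[i]]^2)) * sqrt(sum(vecs[[j]]^2))))
    }
    s <- disagreement_score(com, img)
    expect_equal(s, mean(acc), tolerance = 1e-12)
    expect_true(s >= -1 && s <= 1)
    expect_equal(disagreement_score(com, img, "min"), min(acc), tolerance = 1e-12)
  }
})

test_that("query selection returns the lowest scores with lexicographic ties", {
  com <- stub_committee(list(c(1, 0), c(0, 1)))
  scores <- c(a = 0.9, b = 0.2, c = 0.5)
  expect_identical(select_queries(com, scores = scores, batch = 2L), c("b", "c"))
  expect_identical(select_queries(com, scores = scores, batch = 3L), c("b", "c", "a"))
  ties <- c(d = 0.5, b = 0.5, a = 0.5, c = 0.5)
  expect_identical(select_queries(com, scores = ties, batch = 2L), c("a", "b"))
  expect_error(select_queries(com, scores = scores, batch = 4L),
               class = "handbaa_contract_error")
  # sort oracle on random scores
  set.seed(14)
  sc <- stats::setNames(runif(12), sprintf("id%02d", sample(12)))
  picked <- select_queries(com, scores = sc, batch = 5L)
  oracle <- names(sort(sc))[1:5]
  expect_identical(picked, oracle)
})

make_al_world <- function(n, seed) {
  recs <- generate_phantom_records(n, seed, variation_config(shape = c(32L, 32L)))
  list(records = recs,
       oracle = oracle_from_records(recs),
       ids = vapply(recs, `[[`, character(1), "id"))
}

test_that("the active-learning loop follows the annotation schedule exactly", {
  w <- make_al_world(12, 31)
  labeled <- w$records[1:4]
  unlabeled <- lapply(w$records[5:12], function(r) list(id = r$id, image = r$image))
  calls <- new.env(); calls$n <- 0L
  counting_oracle <- function(id) { calls$n <- calls$n + 1L; w$oracle(id) }
  al <- al_config(k = 2L, initial_labeled = 4L, queries_per_epoch = 2L,
                  query_epochs = 3L, post_epochs = 1L, master_seed = 5L)
  res <- run_active_learning(labeled, unlabeled, counting_oracle, al,
                             micro_net_config())
  expect_identical(res$history$labeled_size, c(6L, 8L, 10L, 10L))
  expect_identical(calls$n, 6L)
  expect_identical(length(res$labeled), 10L)
  # pool conservation: labeled ids are the initial ones plus queried ones
  queried <- unlist(strsplit(res$history$queried[res$history$queried != ""], ";"))
  expect_identical(anyDuplicated(queried), 0L)
  lab_ids <- vapply(res$labeled, `[[`, character(1), "id")
  expect_setequal(lab_ids, c(w$ids[1:4], queried))
  expect_true(all(queried %in% w$ids[5:12]))
  # provenance bookkeeping
  expect_identical(unname(res$provenance[w$ids[1]]), "initial")
  expect_true(all(grepl("^queried-at-epoch-[123]$", res$provenance[queried])))
  # queried scores are reported in ascending order within each epoch
  for (srow in res$history$scores[res$history$queried != ""]) {
    sc <- as.numeric(strsplit(srow, ";")[[1]])
    expect_true(all(diff(sc) >= 0))
  }
})

test_that("the active-learning loop is reproducible from its seeds", {
  w <- make_al_world(10, 33)
  labeled <- w$records[1:4]
  unlabeled <- lapply(w$records[5:10], function(r) list(id = r$id, image = r$image))
  al <- al_config(k = 2L, initial_labeled = 4L, queries_per_epoch = 2L,
                  query_epochs = 2L, post_epochs = 0L, master_seed = 9L)
  r1 <- run_active_learning(labeled, unlabeled, w$oracle, al, micro_net_config())
  r2 <- run_active_learning(labeled, unlabeled, w$oracle, al, micro_net_config())
  expect_identical(r1$history, r2$history)
  expect_identical(r1$committee$members[[1]]$layers,
                   r2$committee$members[[1]]$layers)
})

test_that("a zero-query schedule degenerates to supervised committee training", {
  w <- make_al_world(6, 35)
  labeled <- w$records[1:4]
  unlabeled <- lapply(w$records[5:6], function(r) list(id = r$id, image = r$image))
  boom <- function(id) stop("oracle must not be called")
  al <- al_config(k = 2L, initial_labeled = 4L, queries_per_epoch = 1L,
                  query_epochs = 0L, post_epochs = 2L, master_seed = 2L)
  res <- run_active_learning(labeled, unlabeled, boom, al, micro_net_config())
  expect_identical(res$history$labeled_size, c(4L, 4L))
  expect_identical(length(res$labeled), 4L)
})

test_that("an oracle failure aborts with the offending id", {
  w <- make_al_world(8, 36)
  labeled <- w$records[1:4]
  unlabeled <- lapply(w$records[5:8], function(r) list(id = r$id, image = r$image))
  bad_oracle <- function(id) stop("annotation service down")
  al <- al_config(k = 2L, initial_labeled = 4L, queries_per_epoch = 1L,
                  query_epochs = 1L, post_epochs = 0L, master_seed = 2L)
  expect_error(run_active_learning(labeled, unlabeled, bad_oracle, al,
                                   micro_net_config()),
               "oracle failed for queried id 'ph000",
               class = "handbaa_contract_error")
})

test_that("pool contracts are enforced", {
  w <- make_al_world(6, 37)
  al <- al_config(k = 2L, initial_labeled = 3L, queries_per_epoch = 1L,
                  query_epochs = 1L, post_epochs = 0L)
  expect_error(run_active_learning(w$records[1:4], list(), w$oracle, al,
                                   micro_net_config()),
               class = "handbaa_contract_error")
  dup <- lapply(w$records[3:5], function(r) list(id = r$id, image = r$image))
  expect_error(run_active_learning(w$records[1:3], dup, w$oracle, al,
                                   micro_net_config()),
               class = "handbaa_contract_error")
})

test_that("the supervised baseline uses a fixed seeded budget subset", {
  w <- make_al_world(8, 38)
  m1 <- run_fully_supervised_baseline(w$records, micro_net_config(), epochs = 1L,
                                      budget = 4L, seed = 3L)
  m2 <- run_fully_supervised_baseline(w$records, micro_net_config(), epochs = 1L,
                                      budget = 4L, seed = 3L)
  expect_identical(m1$layers, m2$layers)
  m0 <- run_fully_supervised_baseline(w$records, micro_net_config(), epochs = 0L)
  expect_identical(m0$layers, build_unet(micro_net_config())$layers)
})
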