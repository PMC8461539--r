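test_that("joint probabilities follow the counting and smoothing rules", {
  # one pair, no smoothing: all mass on (x, y)
  m <- build_cooccurrence_model(make_pairs(list("x"), list("y")),
                                list(v_c = "x", v_e = "y"), alpha = 0)
  expect_equal(unname(m$counts["x", "y"]), 1)
  expect_equal(npmi(m, "x", "y"), 1)

  # Laplace smoothing of an empty 2x2 table is uniform
  m <- build_cooccurrence_model(make_pairs(list(), list()),
                                list(v_c = c("a", "b"), v_e = c("u", "v")),
                                alpha = 1)
  p <- riskmine:::model_probabilities(m)
  expect_equal(unname(p$joint), matrix(0.25, 2, 2), tolerance = 1e-15)

  expect_error(
    build_cooccurrence_model(make_pairs(list(), list()),
                             list(v_c = "a", v_e = "u"), alpha = 0),
    class = "riskmine_data_error")
  expect_error(
    build_cooccurrence_model(make_pairs(list("x"), list("y")),
                             list(v_c = character(0), v_e = "y")),
    class = "riskmine_config_error")
})

test_that("pmi matches hand arithmetic and is symmetric in its roles", {
  # two disjoint pairs: marginals 1/2, joint 1/2 => pmi = log 2
  pairs <- make_pairs(list("x", "w"), list("y", "z"))
  vocab <- list(v_c = c("x", "w"), v_e = c("y", "z"))
  m <- build_cooccurrence_model(pairs, vocab, alpha = 0)
  expect_equal(pmi(m, "x", "y"), log(2), tolerance = 1e-12)
  expect_equal(npmi(m, "x", "y"), 1)

  # role swap through the transposed table gives identical pmi
  tpairs <- make_pairs(list("y", "z"), list("x", "w"))
  mt <- build_cooccurrence_model(tpairs,
                                 list(v_c = c("y", "z"), v_e = c("x", "w")),
                                 alpha = 0)
  expect_equal(pmi(mt, "y", "x"), pmi(m, "x", "y"), tolerance = 1e-12)

  expect_error(pmi(m, "nope", "y"), class = "riskmine_lookup_error")
})

test_that("npmi hits its boundary values and base invariance", {
  # independence: joint exactly the product of marginals
  ind <- make_pairs(list("x", "x", "w", "w"), list("y", "z", "y", "z"))
  m <- build_cooccurrence_model(ind,
                                list(v_c = c("x", "w"), v_e = c("y", "z")),
                                alpha = 0)
  expect_equal(npmi(m, "x", "y"), 0, tolerance = 1e-12)

  # never co-occurring, alpha = 0: -1 by convention
  dis <- make_pairs(list("x", "w"), list("u", "y"))
  m <- build_cooccurrence_model(dis,
                                list(v_c = c("x", "w"), v_e = c("u", "y")),
                                alpha = 0)
  expect_equal(npmi(m, "x", "y"), -1)
  expect_equal(pmi(m, "x", "y"), -Inf)

  # base invariance: natural vs base-2 log models agree to 1e-12
  withr::with_seed(5, pairs <- random_pairs(60))
  vocab <- build_phrase_vocabularies(pairs, stopwords = character(0),
                                     min_frequency = 1)
  m_e <- build_cooccurrence_model(pairs, vocab, alpha = 1, log_base = exp(1))
  m_2 <- build_cooccurrence_model(pairs, vocab, alpha = 1, log_base = 2)
  grid <- expand.grid(wc = m_e$v_c[1:4], we = m_e$v_e[1:4],
                      stringsAsFactors = FALSE)
  expect_equal(npmi(m_e, grid$wc, grid$we), npmi(m_2, grid$wc, grid$we),
               tolerance = 1e-12)
  expect_equal(pmi(m_2, grid$wc, grid$we),
               pmi(m_e, grid$wc, grid$we) / log(2), tolerance = 1e-12)
})

test_that("npmi stays in [-1, 1] and smoothing keeps pmi finite", {
  withr::with_seed(17, {
    for (rep in 1:20) {
      pairs <- random_pairs(sample(5:40, 1))
      vocab <- build_phrase_vocabularies(pairs, stopwords = character(0),
                                         min_frequency = 1)
      alpha <- sample(c(0, 0.5, 1, 2), 1)
      m <- build_cooccurrence_model(pairs, vocab, alpha = alpha)
      grid <- expand.grid(wc = m$v_c, we = m$v_e, stringsAsFactors = FALSE)
      vals <- npmi(m, grid$wc, grid$we)
      expect_true(all(vals >= -1 - 1e-12 & vals <= 1 + 1e-12))
      if (alpha > 0) expect_true(all(is.finite(pmi(m, grid$wc, grid$we))))
    }
  })
})

test_that("raising a pair's joint count never lowers its npmi", {
  withr::with_seed(23, {
    pairs <- random_pairs(30)
    vocab <- build_phrase_vocabularies(pairs, stopwords = character(0),
                                       min_frequency = 1)
    m <- build_cooccurrence_model(pairs, vocab, alpha = 1)
    wc <- m$v_c[1]
    we <- m$v_e[1]
    prev <- npmi(m, wc, we)
    for (extra in 1:5) {
      pairs <- dplyr::bind_rows(pairs, make_pairs(list(wc), list(we),
                                                  id = paste0("x", extra)))
      m2 <- build_cooccurrence_model(pairs, vocab, alpha = 1)
      cur <- npmi(m2, wc, we)
      expect_gte(cur, prev - 1e-12)
      prev <- cur
    }
  })
})

test_that("incremental counting equals brute-force recomputation", {
  withr::with_seed(41, {
    for (rep in 1:10) {
      pairs <- random_pairs(25)
      vocab <- build_phrase_vocabularies(pairs, stopwords = character(0),
                                         min_frequency = 1)
      alpha <- sample(c(0, 1), 1)
      m <- build_cooccurrence_model(pairs, vocab, alpha = alpha)
      wc <- sample(m$v_c, 1)
      we <- sample(m$v_e, 1)
      expect_equal(npmi(m, wc, we),
                   bf_npmi(pairs, m$v_c, m$v_e, alpha, wc, we),
                   tolerance = 1e-12)
    }
  })
})

test_that("a co-occurrence model survives the triplet round-trip", {
  withr::with_seed(3, pairs <- random_pairs(40))
  vocab <- build_phrase_vocabularies(pairs, stopwords = character(0),
                                     min_frequency = 1)
  m <- build_cooccurrence_model(pairs, vocab, alpha = 1)
  prefix <- file.path(withr::local_tempdir(), "model")
  write_cooccurrence_model(m, prefix)
  back <- read_cooccurrence_model(prefix)
  expect_equal(back$counts, m$counts)
  expect_equal(back$alpha, m$alpha)
  grid <- expand.grid(wc = m$v_c, we = m$v_e, stringsAsFactors = FALSE)
  expect_equal(npmi(back, grid$wc, grid$we), npmi(m, grid$wc, grid$we),
               tolerance = 1e-12)
})
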