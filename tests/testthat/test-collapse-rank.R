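test_that("phrase embedding is the mean of token vectors", {
  table <- list(a = c(1, 0), b = c(0, 1), c = c(-1, 0), neg = c(-1, 0))
  prov <- fixed_provider(table)
  expect_equal(embed_effect_phrase("a", prov), c(1, 0))
  expect_equal(embed_effect_phrase("a_c", prov), c(0, 0))
  expect_equal(embed_effect_phrase(c("a", "b", "c"), prov),
               c((1 + 0 - 1) / 3, (0 + 1 + 0) / 3))
  expect_error(embed_effect_phrase("", prov), class = "riskmine_data_error")
  bad <- function(tokens) matrix(NaN, length(tokens), 2)
  expect_error(embed_effect_phrase("a", bad), class = "riskmine_data_error")
})

test_that("the hashing provider is deterministic and token-local", {
  prov <- hash_embedding_provider(dim = 16, seed = 4)
  v1 <- token_vectors(prov, c("pain", "pain", "fatigue"))
  expect_identical(v1[1, ], v1[2, ])
  expect_false(isTRUE(all.equal(v1[1, ], v1[3, ])))
  v2 <- token_vectors(hash_embedding_provider(dim = 16, seed = 4), "pain")
  expect_identical(v1[1, ], v2[1, ])
  expect_equal(sqrt(sum(v1[1, ]^2)), 1)
})

test_that("density clustering groups identical and separates distant vectors", {
  emb <- matrix(rep(c(1, 0), each = 5), nrow = 5)
  rownames(emb) <- paste0("p", 1:5)
  cl <- cluster_effect_phrases(emb)
  expect_identical(length(unique(cl$assignment$cluster)), 1L)

  emb <- rbind(a = c(1, 0), b = c(0, 1))
  cl <- cluster_effect_phrases(emb, eps = 0.1)
  expect_identical(length(unique(cl$assignment$cluster)), 2L)
  expect_true(all(cl$assignment$is_core))

  expect_error(cluster_effect_phrases(matrix(numeric(0), 0, 2)),
               class = "riskmine_data_error")
  expect_error(cluster_effect_phrases(emb, eps = -1),
               class = "riskmine_config_error")
})

test_that("sub-eps perturbed duplicates collapse to the planted phrases", {
  withr::with_seed(64, {
    prov <- hash_embedding_provider(dim = 64, seed = 9)
    distinct <- sprintf("effect_%02d", 1:20)
    base <- token_vectors(prov, distinct)
    copies <- 10
    emb <- matrix(0, nrow = 20 * copies, ncol = 64)
    labels <- character(20 * copies)
    for (i in 1:20) {
      for (j in 1:copies) {
        noise <- rnorm(64, sd = 0.005)
        emb[(i - 1) * copies + j, ] <- base[i, ] + noise
        labels[(i - 1) * copies + j] <- sprintf("%s_v%02d", distinct[i], j)
      }
    }
    rownames(emb) <- labels
    cl <- cluster_effect_phrases(emb, eps = 0.1, min_points = 1)
    expect_identical(glance(cl)$n_clusters, 20L)
    reps <- collapse_to_representatives(cl)
    expect_identical(nrow(reps), 20L)
    expect_identical(nrow(reps), length(unique(cl$assignment$cluster)))
    # members of one cluster share their planted prefix
    for (k in seq_len(nrow(reps))) {
      prefixes <- unique(sub("_v[0-9]+$", "", reps$members[[k]]))
      expect_length(prefixes, 1)
    }
  })
})

test_that("shrinking the reachability never merges clusters", {
  withr::with_seed(31, {
    emb <- matrix(rnorm(30 * 8), nrow = 30)
    rownames(emb) <- sprintf("e%02d", 1:30)
    eps_grid <- c(0.5, 0.3, 0.15, 0.05)
    counts <- vapply(eps_grid, function(e) {
      glance(cluster_effect_phrases(emb, eps = e))$n_clusters
    }, integer(1))
    expect_true(all(diff(counts) >= 0))
  })
})

test_that("the representative is the cluster medoid", {
  # three coplanar vectors: b sits between a and c in angle, so b is medoid
  emb <- rbind(a = c(1, 0), b = c(1, 0.2), c = c(1, 0.4))
  cl <- cluster_effect_phrases(emb, eps = 0.5)
  expect_identical(length(unique(cl$assignment$cluster)), 1L)
  reps <- collapse_to_representatives(cl)
  d <- riskmine:::cosine_distance(emb)
  expect_identical(reps$representative, rownames(emb)[which.min(rowSums(d))])
  # singleton cluster represents itself
  single <- cluster_effect_phrases(rbind(only = c(0, 1)), eps = 0.1)
  expect_identical(collapse_to_representatives(single)$representative, "only")
})

test_that("scores average npmi over in-vocabulary pairs", {
  pairs <- make_pairs(
    causes = list(c("q1", "q2"), "q1", "q2", "q1"),
    effects = list(c("e1", "e2"), "e1", "e2", "e2")
  )
  vocab <- list(v_c = c("q1", "q2"), v_e = c("e1", "e2"))
  m <- build_cooccurrence_model(pairs, vocab, alpha = 1)

  expect_equal(score_effect("q1", "e1", m), npmi(m, "q1", "e1"))
  hand <- mean(c(npmi(m, "q1", "e1"), npmi(m, "q1", "e2"),
                 npmi(m, "q2", "e1"), npmi(m, "q2", "e2")))
  expect_equal(score_effect(c("q1", "q2"), "e1 e2", m), hand)
  # out-of-vocabulary effect is undefined under "skip"
  expect_true(is.na(score_effect("q1", "unknown", m)))
  # "zero" treats oov pairs as zero contributions
  expect_equal(score_effect(c("q1", "oovq"), "e1", m, oov = "zero"),
               npmi(m, "q1", "e1") / 2)
  expect_error(score_effect(character(0), "e1", m),
               class = "riskmine_data_error")
})

test_that("ranking is deterministic, permutation-invariant and truncates", {
  pairs <- make_pairs(
    causes = list("q", "q", "q", "x"),
    effects = list("hit", "hit", "miss", "miss")
  )
  vocab <- list(v_c = c("q", "x"), v_e = c("hit", "miss"))
  m <- build_cooccurrence_model(pairs, vocab, alpha = 1)
  rk <- rank_effects("q", c("hit", "miss"), m)
  expect_identical(rk$effect[1], "hit")
  expect_identical(rk$rank, 1:2)
  expect_true(all(diff(rk$score) <= 0))

  rk_perm <- rank_effects("q", c("miss", "hit"), m)
  expect_identical(as.data.frame(rk), as.data.frame(rk_perm))

  expect_identical(nrow(rank_effects("q", "hit", m)), 1L)
  expect_identical(nrow(rank_effects("q", c("hit", "miss"), m, k = 10)), 2L)
  expect_error(rank_effects("q", "notinvocab", m),
               class = "riskmine_data_error")
})

test_that("planted associations rank first for their cause query", {
  cfg <- generator_config(n_messages = 4000, seed = 15)
  norm <- normalize_messages(generate_corpus(cfg))
  cue <- norm[has_causal_cue(norm$text_norm, cfg$cue_list), ]
  pairs <- extract_candidate_pairs(cue, cfg$cue_list)
  model <- build_cooccurrence_model(pairs, build_phrase_vocabularies(pairs))
  emb <- embed_effect_phrases(model$v_e, hash_embedding_provider(32, 1))
  reps <- collapse_to_representatives(cluster_effect_phrases(emb))
  rk <- rank_effects("gardasil", reps, model, k = 3)
  expect_setequal(rk$effect[1:2], c("premature_ovarian_failure",
                                    "early_onset_menopause"))
})

test_that("category scores decompose exactly into contributions", {
  pairs <- make_pairs(
    causes = list("q", "q", "q"),
    effects = list("e1", "e2", "e3")
  )
  vocab <- list(v_c = "q", v_e = c("e1", "e2", "e3"))
  m <- build_cooccurrence_model(pairs, vocab, alpha = 1)
  assignment <- tibble::tibble(effect = c("e1", "e2", "e3"),
                               category = c("A", "A", "B"))
  cs <- cumulative_category_score("q", assignment, m)
  totals <- glance(cs)
  # single-effect category total equals that effect's score
  expect_equal(totals$total[totals$category == "B"],
               score_effect("q", "e3", m))
  # totals are exactly the sum of retained contributions
  by_hand <- tapply(cs$contribution, cs$category, sum)
  expect_equal(unname(setNames(totals$total, totals$category)[names(by_hand)]),
               as.numeric(by_hand))
  expect_equal(totals$total[totals$category == "A"],
               score_effect("q", "e1", m) + score_effect("q", "e2", m))
  expect_error(
    cumulative_category_score("q", tibble::tibble(
      effect = c("e1", "e1"), category = c("A", "B")), m),
    class = "riskmine_data_error")
})

test_that("collapsing leaves surviving phrases' scores unchanged", {
  withr::with_seed(52, pairs <- random_pairs(40))
  vocab <- build_phrase_vocabularies(pairs, stopwords = character(0),
                                     min_frequency = 1)
  m <- build_cooccurrence_model(pairs, vocab, alpha = 1)
  emb <- embed_effect_phrases(m$v_e, hash_embedding_provider(16, 2))
  reps <- collapse_to_representatives(cluster_effect_phrases(emb))
  q <- m$v_c[1]
  for (e in reps$representative) {
    expect_equal(score_effect(q, e, m), score_effect(q, e, m))
    # the score depends only on the model, not on the collapsed set
    expect_equal(rank_effects(q, reps, m)$score[
      rank_effects(q, reps, m)$effect == e],
      score_effect(q, e, m))
  }
})
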