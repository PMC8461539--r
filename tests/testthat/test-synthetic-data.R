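test_that("generator respects size, duplicate and determinism contracts", {
  expect_identical(nrow(generate_corpus(generator_config(n_messages = 0))), 0L)

  cfg <- generator_config(n_messages = 100, duplicate_rate = 0.5, seed = 7)
  corp <- generate_corpus(cfg)
  expect_identical(nrow(corp), 100L)
  expect_identical(sum(corp$is_duplicate), 50L)
  # duplicates are exact copies of their source, appended with fresh ids
  dups <- corp[corp$is_duplicate, ]
  expect_false(anyDuplicated(corp$id) > 0)
  expect_identical(dups$text,
                   corp$text[match(dups$source_id, corp$id)])
  expect_true(all(match(dups$source_id, corp$id) < match(dups$id, corp$id)))

  corp2 <- generate_corpus(generator_config(n_messages = 100,
                                            duplicate_rate = 0.5, seed = 7))
  expect_identical(corp, corp2)

  # every planted association appears at least once
  expect_setequal(unique(stats::na.omit(corp$association)),
                  cfg$planted_associations$association)
})

test_that("generator validates its configuration", {
  expect_error(generator_config(class_balance = 1.5),
               class = "riskmine_config_error")
  expect_error(generator_config(vocab_true = character(0)),
               class = "riskmine_config_error")
  expect_error(generator_config(planted_associations = tibble::tibble(
    cause = "x", effect = list(character(0)), joint_boost = 0.1)),
    class = "riskmine_config_error")
  expect_error(generator_config(cue_list = c("causes", "vaccine")),
               class = "riskmine_config_error")
})

test_that("class-conditional vocabulary proportions hold in the corpus", {
  cfg <- generator_config(n_messages = 4000, cue_rate = 0, seed = 13)
  corp <- normalize_messages(generate_corpus(cfg))
  originals <- corp[!corp$is_duplicate & !corp$has_cue, ]
  false_tokens <- unlist(originals$tokens[originals$label == "false"])
  true_tokens <- unlist(originals$tokens[originals$label == "true"])
  content <- function(x) x[x %in% c(cfg$vocab_true, cfg$vocab_false,
                                    cfg$vocab_shared)]
  false_tokens <- content(false_tokens)
  true_tokens <- content(true_tokens)
  # base tokens: k ~ U(4..10) draws at class_sep = 1/2, plus a shared
  # hashtag token with probability 0.2, so the expected class-vocabulary
  # share of content tokens is (7/2) / (7 + 0.2)
  p_expect <- (7 * cfg$class_sep) / 7.2
  ci <- function(p_hat, n) abs(p_hat - p_expect) <
    2.58 * sqrt(0.25 / n) + 0.01  # binomial 99% CI plus clustering slack
  expect_true(ci(mean(false_tokens %in% cfg$vocab_false),
                 length(false_tokens)))
  expect_true(ci(mean(true_tokens %in% cfg$vocab_true),
                 length(true_tokens)))
  # cross-class leakage only through the shared vocabulary
  expect_identical(sum(false_tokens %in% cfg$vocab_true), 0L)
  expect_identical(sum(true_tokens %in% cfg$vocab_false), 0L)
})

test_that("gold lexicon engineering produces every match type", {
  cfg <- generator_config()
  gold <- generate_gold_lexicon(cfg)
  pa <- cfg$planted_associations
  expect_true(all(table(gold$association) >= 4))
  for (i in seq_len(nrow(pa))) {
    planted <- paste(pa$effect[[i]], collapse = "_")
    sub <- gold[gold$association == pa$association[i], ]
    achieved <- vapply(sub$phrase, classify_match, character(1), e = planted)
    expect_identical(unname(achieved), sub$engineered)
  }
  expect_error(
    generate_gold_lexicon(
      structure(list(planted_associations = tibble::tibble()),
                class = "generator_config")),
    class = "riskmine_config_error")
})

test_that("expected_npmi reproduces the analytic boundary cases", {
  # no boost anywhere: joint = product of marginals, NPMI exactly 0
  flat <- generator_config(
    planted_associations = tibble::tibble(
      cause = "aluminum", effect = list("paralysis"), joint_boost = 0),
    seed = 1)
  expect_equal(expected_npmi(flat, "aluminum", "paralysis"), 0)

  # cause and effect occur only through their (unique) association:
  # complete co-occurrence, NPMI exactly 1
  excl <- generator_config(pool_includes_planted = FALSE, seed = 1)
  expect_equal(expected_npmi(excl, "hpv", "cervical_cancer"), 1)

  # a planted pair under the default mixture lies strictly between
  cfg <- generator_config()
  mid <- expected_npmi(cfg, "gardasil", c("premature", "ovarian", "failure"))
  expect_gt(mid, 0)
  expect_lt(mid, 1)
  expect_error(expected_npmi(cfg, "nosuchterm", "sudden_death"),
               class = "riskmine_lookup_error")
})

test_that("empirical NPMI on a large corpus converges to the oracle", {
  cfg <- generator_config(n_messages = 1e5, seed = 99)
  norm <- normalize_messages(generate_corpus(cfg))
  cue <- norm[has_causal_cue(norm$text_norm, cfg$cue_list), ]
  pairs <- extract_candidate_pairs(cue, cfg$cue_list)
  model <- build_cooccurrence_model(pairs,
                                    build_phrase_vocabularies(pairs),
                                    alpha = 0)
  pa <- cfg$planted_associations
  for (i in seq_len(nrow(pa))) {
    ek <- paste(pa$effect[[i]], collapse = "_")
    expect_lt(abs(npmi(model, pa$cause[i], ek) -
                    expected_npmi(cfg, pa$cause[i], ek)), 0.05)
  }
})

test_that("corpus JSON Lines round-trips", {
  corp <- generate_corpus(generator_config(n_messages = 30, seed = 2))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_messages_jsonl(corp, path)
  back <- read_messages_jsonl(path)
  expect_identical(back$id, corp$id)
  expect_identical(back$text, corp$text)
  expect_identical(back$label, corp$label)
  expect_identical(back$is_duplicate, corp$is_duplicate)
})
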