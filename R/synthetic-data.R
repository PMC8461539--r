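# Synthetic corpus generator with analytic oracles.
#
# The generator emulates the statistical structure the mining pipeline
# assumes: two message classes with partially disjoint vocabularies,
# causal-cue-bearing messages carrying planted cause -> effect assertions of
# known joint probability, retweet-style exact duplicates, and noise
# (mentions, URLs, numerals, hashtags, contractions) for the normalizer to
# clean. Because every cue-bearing message realizes exactly one (cause,
# effect-phrase) assertion, the population NPMI of any term pair has a
# closed form, implemented in expected_npmi().

#' Synthetic corpus generator configuration
#'
#' Defines the study conditions for a simulated message corpus. Cue-bearing
#' messages each assert exactly one (cause term, effect phrase) pair drawn
#' from the mixture `(1 - sum(joint_boost)) * p0(cause) p0(effect) +
#' joint_boost[a]` on the planted pair of association `a`, where `p0` is
#' uniform over the corresponding term pool. This makes the population NPMI
#' of every pair analytically available (see [expected_npmi()]).
#'
#' @param n_messages Number of messages to emit (including duplicates).
#' @param class_balance Fraction of messages in the false-information class.
#' @param vocab_true,vocab_false Class-discriminative term lists.
#' @param vocab_shared Terms common to both classes.
#' @param cue_list Causal cue expressions planted in cue-bearing messages;
#'   must not overlap the vocabulary lists.
#' @param planted_associations Tibble with columns `cause` (character),
#'   `effect` (list-column of character term vectors) and `joint_boost`
#'   (probability mass placed on the exact pair); `sum(joint_boost)` must be
#'   at most 1. An optional `class` column (`"true"`/`"false"`, default all
#'   `"false"`) sets the veracity label of messages carrying the assertion,
#'   emulating that adverse-effect claims circulate as false information.
#' @param background_causes,background_effects Pools for non-planted
#'   assertions; `background_effects` is a list of term vectors.
#' @param pool_includes_planted If `TRUE` (default) the planted causes and
#'   effects are also part of the background pools, so planted pairs get
#'   intermediate NPMI; if `FALSE` each planted term occurs only through its
#'   association and the planted-pair NPMI is exactly 1.
#' @param cue_rate Fraction of original messages that carry a causal
#'   assertion.
#' @param duplicate_rate Fraction of emitted messages that are exact
#'   duplicates of earlier ones.
#' @param class_sep Probability that a base token of a non-cue message is
#'   drawn from the class-specific vocabulary rather than the shared one.
#' @param seed Integer seed; fixed seed implies byte-identical output.
#' @return An object of class `generator_config` (a named list).
#' @export
generator_config <- function(n_messages = 1000,
                             class_balance = 0.5,
                             vocab_true = c("prevent", "protect", "effective",
                                            "safe", "immunity", "prevention"),
                             vocab_false = c("danger", "adverse", "deadly",
                                             "toxic", "harm", "hoax"),
                             vocab_shared = c("vaccine", "hpv", "gardasil",
                                              "girls", "boys", "doctor",
                                              "health", "news", "study",
                                              "people", "shot", "clinic"),
                             cue_list = c("causes", "leads to", "due to",
                                          "triggers", "results in"),
                             planted_associations = default_associations(),
                             background_causes = c("aluminum", "mercury",
                                                   "ingredients", "teens",
                                                   "parents"),
                             background_effects = default_background_effects(),
                             pool_includes_planted = TRUE,
                             cue_rate = 0.3,
                             duplicate_rate = 0.1,
                             class_sep = 0.5,
                             seed = 1L) {
  n_messages <- assert_count(n_messages, "n_messages", min = 0L)
  assert_probability(class_balance, "class_balance")
  assert_probability(cue_rate, "cue_rate")
  assert_probability(duplicate_rate, "duplicate_rate")
  assert_probability(class_sep, "class_sep")
  seed <- assert_count(seed, "seed", min = 0L)
  for (v in list(vocab_true = vocab_true, vocab_false = vocab_false,
                 vocab_shared = vocab_shared)) {
    if (length(v) == 0) config_error("vocabulary lists must be nonempty")
  }
  pa <- as_tibble(planted_associations)
  if (nrow(pa) == 0) config_error("planted_associations must be nonempty")
  if (!all(c("cause", "effect", "joint_boost") %in% names(pa))) {
    config_error("planted_associations needs columns cause, effect, joint_boost")
  }
  if (!is.list(pa$effect)) pa$effect <- as.list(pa$effect)
  if (any(lengths(pa$effect) == 0)) {
    config_error("planted effect phrases must be nonempty")
  }
  if (!"class" %in% names(pa)) pa$class <- "false"
  if (!all(pa$class %in% c("true", "false"))) {
    config_error("planted association classes must be 'true' or 'false'")
  }
  if (any(pa$joint_boost < 0) || sum(pa$joint_boost) > 1) {
    config_error("joint_boost values must be nonnegative and sum to at most 1")
  }
  pa$association <- sprintf("assoc%02d", seq_len(nrow(pa)))
  cue_tokens <- unlist(strsplit(cue_list, " ", fixed = TRUE))
  if (any(cue_tokens %in% c(vocab_true, vocab_false, vocab_shared))) {
    config_error("cue expressions must not overlap the vocabulary lists")
  }
  structure(
    list(n_messages = n_messages, class_balance = class_balance,
         vocab_true = vocab_true, vocab_false = vocab_false,
         vocab_shared = vocab_shared, cue_list = cue_list,
         planted_associations = pa,
         background_causes = background_causes,
         background_effects = background_effects,
         pool_includes_planted = pool_includes_planted,
         cue_rate = cue_rate, duplicate_rate = duplicate_rate,
         class_sep = class_sep, seed = seed),
    class = "generator_config"
  )
}

# Default planted associations: five vaccine risk-perception assertions in
# the style the mining pipeline is built to recover.
default_associations <- function() {
  tibble(
    cause = c("gardasil", "gardasil", "vaccine", "vaccine", "hpv"),
    effect = list(c("premature", "ovarian", "failure"),
                  c("early", "onset", "menopause"),
                  c("sudden", "death"),
                  c("extreme", "fatigue"),
                  c("cervical", "cancer")),
    joint_boost = c(0.10, 0.08, 0.08, 0.06, 0.08),
    class = c("false", "false", "false", "false", "true")
  )
}

default_background_effects <- function() {
  list("paralysis", "stroke", "autism", "seizures", "recall",
       c("chronic", "pain"), c("memory", "loss"), c("hair", "loss"),
       c("blood", "clots"), "headaches", "dizziness", "fainting",
       c("immune", "disorder"), c("heart", "problems"), "rashes")
}

effect_key <- function(terms) paste(terms, collapse = "_")

# Mixture components shared by the generator and the analytic oracle.
assertion_pools <- function(config) {
  pa <- config$planted_associations
  causes <- unique(pa$cause)
  effects <- unique(vapply(pa$effect, effect_key, character(1)))
  if (config$pool_includes_planted) {
    pool_c <- unique(c(causes, config$background_causes))
    pool_e <- unique(c(effects,
                       vapply(config$background_effects, effect_key,
                              character(1))))
  } else {
    pool_c <- setdiff(unique(config$background_causes), causes)
    pool_e <- setdiff(unique(vapply(config$background_effects, effect_key,
                                    character(1))), effects)
    if (length(pool_c) == 0 || length(pool_e) == 0) {
      config_error("background pools must be nonempty when they exclude planted terms")
    }
  }
  list(pool_c = pool_c, pool_e = pool_e, boost = sum(pa$joint_boost))
}

#' Generate a synthetic message corpus
#'
#' Draws messages according to a [generator_config()]: class labels from
#' `class_balance`; non-cue messages as noisy bags of class and shared
#' vocabulary; cue-bearing messages as `"<noise> the <cause> <cue> the
#' <effect terms> <noise>"` with the (cause, effect) pair drawn from the
#' configured mixture; and finally exact duplicates appended after the
#' originals with fresh ids. Every planted association is guaranteed to
#' appear in at least one message. All randomness comes from a single stream
#' seeded by `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A tibble with columns `id`, `text`, `label`, `is_duplicate`,
#'   `source_id`, `has_cue`, `association` (planted association id or `NA`),
#'   `cause`, `effect` (list-column of effect terms).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_messages
  empty <- tibble(id = character(), text = character(), label = character(),
                  is_duplicate = logical(), source_id = character(),
                  has_cue = logical(), association = character(),
                  cause = character(), effect = list())
  if (n == 0) return(empty)
  withr::with_seed(config$seed, {
    n_dup <- round(n * config$duplicate_rate)
    n_orig <- n - n_dup
    if (n_orig == 0) config_error("duplicate_rate leaves no original messages")
    label <- ifelse(runif(n_orig) < config$class_balance, "false", "true")
    has_cue <- runif(n_orig) < config$cue_rate
    pa <- config$planted_associations
    pools <- assertion_pools(config)

    # draw one assertion per cue-bearing message
    n_cue <- sum(has_cue)
    assoc_idx <- rep(NA_integer_, n_orig)
    cause <- rep(NA_character_, n_orig)
    effect <- vector("list", n_orig)
    if (n_cue > 0) {
      u <- runif(n_cue)
      cuts <- cumsum(pa$joint_boost)
      idx <- findInterval(u, c(0, cuts), rightmost.closed = FALSE)
      idx[u >= pools$boost] <- NA_integer_  # background draw
      which_cue <- which(has_cue)
      assoc_idx[which_cue] <- idx
      planted <- which_cue[!is.na(idx)]
      cause[planted] <- pa$cause[idx[!is.na(idx)]]
      effect[planted] <- pa$effect[idx[!is.na(idx)]]
      # a planted assertion determines its message's veracity class
      label[planted] <- pa$class[idx[!is.na(idx)]]
      bg <- which_cue[is.na(idx)]
      if (length(bg) > 0) {
        cause[bg] <- sample(pools$pool_c, length(bg), replace = TRUE)
        effect[bg] <- strsplit(sample(pools$pool_e, length(bg),
                                      replace = TRUE), "_", fixed = TRUE)
      }
    }
    # guarantee every planted association appears at least once
    missing <- which(!seq_len(nrow(pa)) %in% assoc_idx)
    for (a in missing) {
      slot <- which(has_cue & is.na(assoc_idx))
      target <- if (length(slot) > 0) slot[1] else which(!has_cue)[1]
      if (is.na(target)) target <- 1L
      has_cue[target] <- TRUE
      assoc_idx[target] <- a
      cause[target] <- pa$cause[a]
      effect[target] <- pa$effect[a]
      label[target] <- pa$class[a]
    }

    text <- character(n_orig)
    for (i in seq_len(n_orig)) {
      text[i] <- if (has_cue[i]) {
        compose_cue_message(cause[i], effect[[i]], config)
      } else {
        compose_base_message(label[i], config)
      }
    }

    out <- tibble(
      id = sprintf("msg%06d", seq_len(n_orig)),
      text = text, label = label,
      is_duplicate = FALSE, source_id = NA_character_,
      has_cue = has_cue,
      association = ifelse(is.na(assoc_idx), NA_character_,
                           pa$association[assoc_idx]),
      cause = cause, effect = effect
    )
    if (n_dup > 0) {
      src <- sample.int(n_orig, n_dup, replace = TRUE)
      dup <- out[src, ]
      dup$id <- sprintf("msg%06d", n_orig + seq_len(n_dup))
      dup$is_duplicate <- TRUE
      dup$source_id <- out$id[src]
      out <- bind_rows(out, dup)
    }
    out
  })
}

# "<RT @user:>? the <cause> <cue> the <effect...> <url/punct>?"
# The leading stopword isolates the cause term as its own noun chunk; noise
# is confined to removable material so the assertion survives normalization
# intact.
compose_cue_message <- function(cause, effect_terms, config) {
  cue <- sample(config$cue_list, 1)
  parts <- c(
    if (runif(1) < 0.15) sprintf("RT @user%03d:", sample.int(999, 1)),
    "the", cause, cue, "the", paste(effect_terms, collapse = " ")
  )
  if (runif(1) < 0.3) parts <- c(parts, sprintf("https://t.co/%06x", sample.int(2^24, 1) - 1L))
  if (runif(1) < 0.2) parts <- c(parts, sample(c("!!!", "?!", "..."), 1))
  paste(parts, collapse = " ")
}

compose_base_message <- function(label, config) {
  class_vocab <- if (label == "false") config$vocab_false else config$vocab_true
  k <- sample(4:10, 1)
  from_class <- runif(k) < config$class_sep
  words <- ifelse(from_class,
                  sample(class_vocab, k, replace = TRUE),
                  sample(config$vocab_shared, k, replace = TRUE))
  if (runif(1) < 0.2) {
    m <- sample(c(1, 3), 1)  # runs of 3 exercise the MENTION collapse rule
    words <- c(sprintf("@user%03d", sample.int(999, m)), words)
  }
  if (runif(1) < 0.2) words <- append(words, sample(c("3,000", "2x", "90%"), 1),
                                      after = sample.int(length(words), 1))
  if (runif(1) < 0.2) words <- c(words, paste0("#", sample(config$vocab_shared, 1)))
  if (runif(1) < 0.15) words <- c(sample(c("Can't", "Won't", "You'll"), 1), words)
  if (runif(1) < 0.2) words <- c(words, sprintf("https://t.co/%06x", sample.int(2^24, 1) - 1L))
  if (runif(1) < 0.15) words[1] <- paste0(toupper(substr(words[1], 1, 1)),
                                          substr(words[1], 2, nchar(words[1])))
  paste(words, collapse = " ")
}

#' Generate a gold risk-perception lexicon matched to the planted effects
#'
#' For each planted effect phrase, emits gold phrases engineered to produce
#' each candidate-vs-gold match type: an `exact` copy; a `proper` target (a
#' strict sub-phrase, so the mined effect is the more specific form); one or
#' two `reverse` targets (strict super-phrases); and a `partial` target
#' (overlapping but neither containing the other) when the effect has at
#' least two terms. Each association gets its own category label, emulating
#' a consumer risk-perception lexicon organised by category.
#'
#' @param config A [generator_config()].
#' @return A tibble with columns `phrase`, `category`, `engineered` (the
#'   match type the phrase is designed to elicit), `association`.
#' @export
generate_gold_lexicon <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  pa <- config$planted_associations
  if (nrow(pa) == 0) config_error("planted_associations must be nonempty")
  rows <- purrr::pmap(list(pa$effect, pa$association, seq_len(nrow(pa))),
                      function(terms, assoc, i) {
    category <- sprintf("category_%02d", i)
    phrases <- list(
      tibble(phrase = paste(terms, collapse = " "), engineered = "exact")
    )
    if (length(terms) >= 2) {
      phrases <- c(phrases, list(
        tibble(phrase = paste(terms[-1], collapse = " "), engineered = "proper"),
        tibble(phrase = paste(c(terms[-length(terms)], "syndrome"),
                              collapse = " "), engineered = "partial")
      ))
    }
    phrases <- c(phrases, list(
      tibble(phrase = paste(c("severe", terms), collapse = " "),
             engineered = "reverse"),
      tibble(phrase = paste(c("chronic", terms), collapse = " "),
             engineered = "reverse")
    ))
    bind_rows(phrases) %>%
      mutate(category = category, association = assoc)
  })
  bind_rows(rows) %>% select("phrase", "category", "engineered", "association")
}

#' Population NPMI implied by a generator configuration
#'
#' Closed-form (unsmoothed) normalized pointwise mutual information of a
#' (cause term, effect phrase) pair under the generator's assertion mixture.
#' With `q` the pair's joint probability and `p_c`, `p_e` its marginals over
#' the assertion distribution, the value is `log(q / (p_c p_e)) / (-log q)`,
#' with the conventions `q = 0 -> -1` and `q = 1 -> 1`.
#'
#' @param config A [generator_config()].
#' @param cause_term A cause term known to the configuration.
#' @param effect_term An effect phrase, given either as its underscore-joined
#'   key (`"sudden_death"`) or as a character vector of terms.
#' @return A single number in `[-1, 1]`.
#' @export
expected_npmi <- function(config, cause_term, effect_term) {
  stopifnot(inherits(config, "generator_config"))
  if (length(effect_term) > 1) effect_term <- effect_key(effect_term)
  pa <- config$planted_associations
  pools <- assertion_pools(config)
  planted_c <- unique(pa$cause)
  planted_e <- vapply(pa$effect, effect_key, character(1))
  known_c <- unique(c(pools$pool_c, planted_c))
  known_e <- unique(c(pools$pool_e, planted_e))
  if (!cause_term %in% known_c) {
    lookup_error(sprintf("unknown cause term '%s'", cause_term))
  }
  if (!effect_term %in% known_e) {
    lookup_error(sprintf("unknown effect phrase '%s'", effect_term))
  }
  base <- 1 - pools$boost
  p0c <- if (cause_term %in% pools$pool_c) 1 / length(pools$pool_c) else 0
  p0e <- if (effect_term %in% pools$pool_e) 1 / length(pools$pool_e) else 0
  j <- sum(pa$joint_boost[pa$cause == cause_term & planted_e == effect_term])
  q <- base * p0c * p0e + j
  p_c <- base * p0c + sum(pa$joint_boost[pa$cause == cause_term])
  p_e <- base * p0e + sum(pa$joint_boost[planted_e == effect_term])
  npmi_value(q, p_c, p_e)
}

# Shared NPMI arithmetic with the boundary conventions.
npmi_value <- function(q, p_c, p_e) {
  if (q <= 0) return(-1)
  if (q >= 1) return(1)
  log(q / (p_c * p_e)) / (-log(q))
}
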