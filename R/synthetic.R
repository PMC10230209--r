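# Synthetic rosters with latent ground truth. The generator emulates the
# structure the validation assumes: latent persons with repeated service
# contacts, a small number of cross-gender service-number collisions,
# missing key fields, and reversible formatting noise.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration for the synthetic roster generator
#'
#' Defaults reflect a mid-sized charity roster of the kind the validation
#' targets: about 2.3k distinct individuals producing 2.6k service
#' contacts in a year, ten pairs of distinct individuals sharing a service
#' number but differing in gender, a 2% chance that either key field is
#' missing, and a 5% chance a record's fields carry formatting noise
#' (case, whitespace, spelled-out gender) that normalization reverses.
#'
#' @param n_persons Number of distinct individuals.
#' @param n_records Number of roster records (service contacts),
#'   `>= n_persons`; every person contributes at least one record and the
#'   remainder are allocated with a geometric-tailed contacts-per-person
#'   distribution (exponential person weights, so a few heavy users).
#' @param collision_pairs Number of person pairs planted to share one
#'   service number with discordant gender, `<= n_persons / 2`. These are
#'   the duplicates the two-field hash identifier resolves and the
#'   gold-standard key cannot.
#' @param missing_rate Per-field probability that a record's gender or
#'   service number is blanked (applied after noise).
#' @param noise_rate Probability a record's fields are format-mangled.
#' @param p_male Probability a non-collision person is male; collision
#'   pairs are one of each by construction.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#'   `NULL` uses (and advances) the current RNG state.
#' @return Object of class `"roster_config"`.
#' @export
roster_config <- function(n_persons = 2306, n_records = 2622,
                          collision_pairs = 10, missing_rate = 0.02,
                          noise_rate = 0.05, p_male = 0.9, seed = NULL) {
  stopifnot(n_persons >= 1, n_records >= n_persons,
            missing_rate >= 0, missing_rate <= 1,
            noise_rate >= 0, noise_rate <= 1,
            p_male >= 0, p_male <= 1)
  if (collision_pairs < 0 || collision_pairs > n_persons / 2) {
    stop("collision_pairs must be between 0 and n_persons / 2", call. = FALSE)
  }
  structure(
    list(n_persons = as.integer(n_persons), n_records = as.integer(n_records),
         collision_pairs = as.integer(collision_pairs),
         missing_rate = missing_rate, noise_rate = noise_rate,
         p_male = p_male, seed = seed),
    class = "roster_config"
  )
}

#' Generator configuration whose clean roster matches given margins
#'
#' Convenience wrapper: builds a noiseless, fully observed configuration
#' whose cleaned roster has exactly `n_records` records, `n_gold` distinct
#' service numbers and `n_hash` distinct (gender, service number) pairs —
#' i.e. `n_hash - n_gold` planted cross-gender collisions. Used to
#' reconstruct published cross-tabulations from their margins.
#'
#' @param n_records Total records.
#' @param n_gold Distinct service numbers (gold-key groups).
#' @param n_hash Distinct (gender, service number) pairs (hash-key
#'   groups); `n_gold <= n_hash <= n_records`.
#' @param seed Integer seed.
#' @return A `"roster_config"`.
#' @examples
#' cfg <- margins_config(n_records = 2622, n_gold = 2296, n_hash = 2306, seed = 1)
#' @export
margins_config <- function(n_records, n_gold, n_hash, seed = NULL) {
  stopifnot(n_gold <= n_hash, n_hash <= n_records)
  roster_config(n_persons = n_hash, n_records = n_records,
                collision_pairs = n_hash - n_gold,
                missing_rate = 0, noise_rate = 0, seed = seed)
}

#' Simulate the latent population
#'
#' Persons get unique service numbers (two letters + six digits) except
#' the planted collision pairs, each of which shares one service number
#' between a male and a female person.
#'
#' @param config A [roster_config()].
#' @return Data frame with `person_id`, `gender`, `service_number`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "roster_config"))
  with_seed(config$seed, {
    n <- config$n_persons
    k <- config$collision_pairs
    n_sn <- n - k
    sn <- character(0L)
    while (length(sn) < n_sn) {
      need <- n_sn - length(sn)
      cand <- paste0(
        sample(LETTERS, need, replace = TRUE),
        sample(LETTERS, need, replace = TRUE),
        sprintf("%06d", sample.int(1e6, need, replace = TRUE) - 1L)
      )
      sn <- unique(c(sn, cand))
    }
    gender <- ifelse(stats::rbinom(n, 1L, config$p_male) == 1L, "M", "F")
    service_number <- character(n)
    if (k > 0L) {
      # persons 1..2k form the collision pairs: pair i shares sn[i], M + F
      pair_sn <- sn[seq_len(k)]
      service_number[seq_len(2L * k)] <- rep(pair_sn, each = 2L)
      gender[seq_len(2L * k)] <- rep(c("M", "F"), times = k)
    }
    if (n_sn > k) {
      service_number[(2L * k + 1L):n] <- sn[(k + 1L):n_sn]
    }
    perm <- sample.int(n)
    data.frame(person_id = seq_len(n),
               gender = gender[perm],
               service_number = service_number[perm],
               stringsAsFactors = FALSE)
  })
}

mangle_gender <- function(g, which) {
  full <- ifelse(g == "M", "Male", "Female")
  switch(which,
         tolower(g),
         paste0(" ", g, " "),
         full,
         tolower(full))
}

mangle_sn <- function(s, which) {
  mid <- nchar(s) %/% 2L
  switch(which,
         tolower(s),
         paste0("  ", s),
         paste0(substr(s, 1L, mid), " ", substr(s, mid + 1L, nchar(s))),
         paste0(tolower(s), " "))
}

#' Simulate a roster of service contacts with ground truth
#'
#' Every person contributes at least one record; the remaining
#' `n_records - n_persons` contacts are allocated with exponential person
#' weights, giving a geometric-tailed contacts-per-person distribution.
#' Formatting noise is applied first and is reversible (normalization
#' recovers the canonical value); missingness is applied after noise.
#' Record order is shuffled. Two auxiliary columns (`contact_date`,
#' `support_type`) are carried but never inspected by any computation.
#'
#' @param config A [roster_config()].
#' @param population Optional population from [simulate_population()];
#'   generated from `config` when omitted. Note that when supplied
#'   together with a non-`NULL` seed, the same seed drives both stages.
#' @return Object of class `"synthetic_roster"`: list with `roster` (the
#'   raw data frame to feed the pipeline), `truth` (per-record
#'   `person_id`, canonical `gender_true`/`service_number_true`,
#'   `noised`, `missing_gender`, `missing_service_number`),
#'   `population`, and `config`.
#' @examples
#' sim <- simulate_roster(roster_config(n_persons = 50, n_records = 80,
#'                                      collision_pairs = 2, seed = 42))
#' head(sim$roster)
#' oracle_statistics(sim)$crosstab
#' @export
simulate_roster <- function(config, population = NULL) {
  stopifnot(inherits(config, "roster_config"))
  if (is.null(population)) population <- simulate_population(config)
  with_seed(if (is.null(config$seed)) NULL else config$seed + 1L, {
    n <- config$n_persons
    extras <- config$n_records - n
    w <- stats::rexp(n)
    counts <- rep(1L, n)
    if (extras > 0L) {
      counts <- counts + tabulate(
        sample.int(n, extras, replace = TRUE, prob = w / sum(w)), nbins = n)
    }
    who <- rep(seq_len(n), times = counts)
    who <- who[sample.int(length(who))]
    m <- length(who)

    gender_raw <- population$gender[who]
    sn_raw <- population$service_number[who]
    gender_true <- gender_raw
    sn_true <- sn_raw

    noised <- stats::runif(m) < config$noise_rate
    if (any(noised)) {
      idx <- which(noised)
      gv <- sample.int(4L, length(idx), replace = TRUE)
      sv <- sample.int(4L, length(idx), replace = TRUE)
      gender_raw[idx] <- mapply(mangle_gender, gender_raw[idx], gv)
      sn_raw[idx] <- mapply(mangle_sn, sn_raw[idx], sv)
    }
    miss_g <- stats::runif(m) < config$missing_rate
    miss_s <- stats::runif(m) < config$missing_rate
    gender_raw[miss_g] <- NA_character_
    sn_raw[miss_s] <- NA_character_

    roster <- data.frame(
      gender = gender_raw,
      service_number = sn_raw,
      contact_date = as.character(
        as.Date("2021-01-01") + sample.int(365L, m, replace = TRUE) - 1L),
      support_type = sample(c("housing", "welfare", "health", "employment"),
                            m, replace = TRUE),
      stringsAsFactors = FALSE
    )
    truth <- data.frame(
      person_id = population$person_id[who],
      gender_true = gender_true,
      service_number_true = sn_true,
      noised = noised,
      missing_gender = miss_g,
      missing_service_number = miss_s,
      stringsAsFactors = FALSE
    )
    structure(list(roster = roster, truth = truth,
                   population = population, config = config),
              class = "synthetic_roster")
  })
}

#' @export
print.synthetic_roster <- function(x, ...) {
  cat("Synthetic roster: ", nrow(x$roster), " records, ",
      x$config$n_persons, " persons, ",
      x$config$collision_pairs, " planted collision pair(s)\n", sep = "")
  invisible(x)
}

#' Expected statistics from generator ground truth
#'
#' Computes, by brute-force grouping on the latent truth fields and
#' independently of the pipeline's normalization and hashing code paths,
#' the cross-tabulation and accuracy statistics the pipeline should
#' produce on the cleaned roster: records with either key field missing
#' are dropped (formatting noise is reversible, so noised records
#' survive), primaries are flagged by first occurrence of the true key
#' values, and the four cells are counted directly.
#'
#' @param sim A `"synthetic_roster"`.
#' @return List with `crosstab` (named vector a, b, c, d, n),
#'   `sensitivity`, `specificity`, `n_excluded`, `n_distinct_gold`,
#'   `n_distinct_hash`.
#' @export
oracle_statistics <- function(sim) {
  stopifnot(inherits(sim, "synthetic_roster"))
  tr <- sim$truth
  keep <- !tr$missing_gender & !tr$missing_service_number
  g <- tr$gender_true[keep]
  s <- tr$service_number_true[keep]
  pair <- paste(g, s, sep = "\r")
  gp <- !duplicated(s)
  hp <- !duplicated(pair)
  a <- sum(gp & hp); b <- sum(!gp & hp); cc <- sum(gp & !hp); d <- sum(!gp & !hp)
  list(
    crosstab = c(a = a, b = b, c = cc, d = d, n = length(g)),
    sensitivity = if (a + cc > 0) a / (a + cc) else NA_real_,
    specificity = if (b + d > 0) d / (b + d) else NA_real_,
    n_excluded = sum(!keep),
    n_distinct_gold = length(unique(s)),
    n_distinct_hash = length(unique(pair))
  )
}
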