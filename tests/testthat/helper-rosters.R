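# Shared fixture builders for the test suite.

# a tiny hand-written roster with known structure
toy_roster <- function() {
  data.frame(
    gender = c("M", "F", "M", " male ", "F"),
    service_number = c("AB123456", "AB123456", "CD000001", "cd 000001", "EF999999"),
    note = letters[1:5],
    stringsAsFactors = FALSE
  )
}

# random generator configuration for property sweeps
random_config <- function(seed, missing_max = 0.1, noise_max = 0.5) {
  set.seed(seed * 1009L)
  n_persons <- sample(20:60, 1L)
  roster_config(
    n_persons = n_persons,
    n_records = n_persons + sample(0:40, 1L),
    collision_pairs = sample(0:5, 1L),
    missing_rate = stats::runif(1L, 0, missing_max),
    noise_rate = stats::runif(1L, 0, noise_max),
    seed = seed
  )
}

# two rosters over populations sharing exactly `overlap` persons
shared_person_rosters <- function(n_left, n_right, overlap, seed,
                                  records_left = NULL, records_right = NULL) {
  stopifnot(overlap <= n_left, overlap <= n_right)
  total <- n_left + n_right - overlap
  pop <- simulate_population(roster_config(
    n_persons = total, n_records = total, collision_pairs = 0L,
    missing_rate = 0, noise_rate = 0, seed = seed))
  left_pop <- pop[seq_len(n_left), , drop = FALSE]
  right_pop <- pop[(n_left - overlap + 1L):total, , drop = FALSE]
  mk <- function(p, n_records, s) {
    simulate_roster(
      roster_config(n_persons = nrow(p), n_records = n_records,
                    collision_pairs = 0L, missing_rate = 0, noise_rate = 0,
                    seed = s),
      population = p)
  }
  list(
    left = mk(left_pop, if (is.null(records_left)) n_left + 10L else records_left,
              seed + 1L),
    right = mk(right_pop, if (is.null(records_right)) n_right + 10L else records_right,
               seed + 2L)
  )
}
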