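# shared fixtures: small, fast synthetic worlds built in code

small_config <- function(seed = 42, n_zones = 24, ...) {
  synth_config(seed = seed, n_zones = n_zones, ...)
}

small_study <- function(seed = 42, n_zones = 24, ...) {
  generate_study(small_config(seed = seed, n_zones = n_zones, ...))
}

# brute-force decile scoring oracle: sort, rank (ties share the lower
# rank), bin by ceil(10 * rank / n)
oracle_decile_scores <- function(values) {
  r <- rank(values, ties.method = "min")
  as.integer(ceiling(10 * r / length(values)))
}

# hand-rolled Pearson r via the covariance / sd formula
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# a tiny hand-built stratified population/cases world for SIR checks
toy_sir_world <- function() {
  population <- data.frame(
    zone_id = rep(c("A", "B"), each = 2),
    age_band = rep(c("young", "old"), 2),
    sex = "F",
    pop = c(10000, 5000, 20000, 1000),
    stringsAsFactors = FALSE
  )
  rates <- standard_rates(data.frame(
    age_band = c("young", "old"), sex = "F", rate = c(100, 400)
  ))
  list(population = population, rates = rates)
}
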