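# shared fixtures, built in code

# constant-rate life table (single stratum unless sexes = TRUE)
lt_const <- function(rate, ages = 0:99, years = 2005:2019, sexes = FALSE) {
  if (sexes)
    life_table(expand.grid(age = ages, year = years,
                           sex = c("male", "female"), rate = rate,
                           stringsAsFactors = FALSE))
  else
    life_table(expand.grid(age = ages, year = years, rate = rate))
}

lt_gomp <- make_gompertz_life_table()

sc1_covs <- c("agec", "sex", "X1", "X2")

# independent PGW formulas straight from the closed-form survival function,
# used as oracles (deliberately not the package implementation)
pgw_S0 <- function(t, s, v, g) exp(1 - (1 + (t / s)^v)^(1 / g))
pgw_H0 <- function(t, s, v, g) (1 + (t / s)^v)^(1 / g) - 1
pgw_h0 <- function(t, s, v, g)
  (v / (g * s)) * (t / s)^(v - 1) * (1 + (t / s)^v)^(1 / g - 1)
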