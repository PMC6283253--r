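# Synthetic example species, hand-checkable toy models, schedule-table
# I/O, and an individual-based Monte Carlo simulator used as an
# independent check on the analytic Markov chain results.
#
# The example species is a hypothetical poecilogonous marine invertebrate:
# four stages (small juvenile JS, large juvenile JL, small[-born] adult
# AS, large[-born] adult AL), with two offspring types differing in
# parental investment. Large-born individuals survive better at every
# age, mature earlier and to a higher plateau, and adults of both types
# produce more of the cheap small offspring, with a heritability
# asymmetry (large adults produce relatively more large offspring).
# The parametric curves here are synthetic stand-ins with those
# qualitative features; exact published schedules for a real study would
# be supplied through load_schedule_table().

#' Configuration for the synthetic example species
#'
#' Parametric age curves for the 4-stage life cycle. Juvenile and adult
#' survival are age-constant by default (optionally with a gentle logistic
#' senescent decline in adult survival); maturation probabilities are
#' logistic in age, rising to a plateau, with earlier onset and a higher
#' plateau for large juveniles; fertilities ramp up logistically after
#' maturation, small offspring being produced at higher rates by both
#' adult types and each adult type favoring its own offspring type.
#'
#' @param omega Number of age classes (default 50).
#' @param sigma_JS,sigma_JL Juvenile survival probabilities per time step
#'   (small, large).
#' @param sigma_AS,sigma_AL Adult survival probabilities per time step.
#' @param gamma_max Length-2 vector: maturation plateau for small and
#'   large juveniles.
#' @param gamma_mid Length-2 vector: age at half-maximal maturation.
#' @param gamma_rate Logistic steepness of the maturation curves.
#' @param f_max Length-4 vector of plateau fertilities
#'   `(f_SS, f_SL, f_LS, f_LL)`: production of small/large offspring by
#'   small adults, then by large adults.
#' @param fert_mid,fert_rate Age at half-maximal fertility and logistic
#'   steepness.
#' @param senescence If `TRUE`, adult survival declines logistically with
#'   age.
#' @param sen_mid,sen_rate Midpoint and steepness of the senescent
#'   decline.
#' @return An object of class `agestage_species_config`.
#' @export
species_config <- function(omega = 50,
                           sigma_JS = 0.30, sigma_JL = 0.55,
                           sigma_AS = 0.90, sigma_AL = 0.95,
                           gamma_max = c(0.6, 0.8),
                           gamma_mid = c(6, 4),
                           gamma_rate = 1.5,
                           f_max = c(f_SS = 1.6, f_SL = 0.16, f_LS = 1.0, f_LL = 0.5),
                           fert_mid = 8, fert_rate = 2,
                           senescence = FALSE,
                           sen_mid = 35, sen_rate = 5) {
  cfg <- list(omega = omega, sigma_JS = sigma_JS, sigma_JL = sigma_JL,
              sigma_AS = sigma_AS, sigma_AL = sigma_AL,
              gamma_max = gamma_max, gamma_mid = gamma_mid,
              gamma_rate = gamma_rate, f_max = f_max,
              fert_mid = fert_mid, fert_rate = fert_rate,
              senescence = senescence, sen_mid = sen_mid,
              sen_rate = sen_rate)
  class(cfg) <- "agestage_species_config"
  cfg
}

schedule_columns <- c("sigma_JS", "sigma_JL", "sigma_AS", "sigma_AL",
                      "gamma_S", "gamma_L",
                      "f_SS", "f_SL", "f_LS", "f_LL")

#' Age-schedule table for the example species
#'
#' Evaluates the configured parametric curves at age classes `1..omega`,
#' returning one row per age class with the ten life-history columns
#' (stage-specific survival, maturation, and fertility).
#'
#' @param config An `agestage_species_config`.
#' @return Data frame with columns `age` and the ten schedule columns.
#' @export
species_schedule_table <- function(config = species_config()) {
  stopifnot(inherits(config, "agestage_species_config"))
  x <- seq_len(config$omega)
  logistic <- function(x, mid, rate) 1 / (1 + exp(-(x - mid) / rate))
  sen <- if (config$senescence) {
    0.6 + 0.4 / (1 + exp((x - config$sen_mid) / config$sen_rate))
  } else rep(1, config$omega)
  fert <- logistic(x, config$fert_mid, config$fert_rate)
  tab <- data.frame(
    age = x,
    sigma_JS = rep(config$sigma_JS, config$omega),
    sigma_JL = rep(config$sigma_JL, config$omega),
    sigma_AS = config$sigma_AS * sen,
    sigma_AL = config$sigma_AL * sen,
    gamma_S = config$gamma_max[1] * logistic(x, config$gamma_mid[1], config$gamma_rate),
    gamma_L = config$gamma_max[2] * logistic(x, config$gamma_mid[2], config$gamma_rate),
    f_SS = config$f_max[[1]] * fert,
    f_SL = config$f_max[[2]] * fert,
    f_LS = config$f_max[[3]] * fert,
    f_LL = config$f_max[[4]] * fert
  )
  tab
}

#' Build schedules from an age-schedule table
#'
#' Assembles the per-age stage matrices in the example species' sparsity
#' pattern: juveniles survive and either stay juvenile or mature into
#' their own adult type,
#' `U_x[1,1] = sigma_JS (1 - gamma_S)`, `U_x[3,1] = sigma_JS gamma_S`,
#' etc., and only adults reproduce, into the two juvenile rows
#' (`F_x[1,3] = f_SS`, `F_x[1,4] = f_LS`, `F_x[2,3] = f_SL`,
#' `F_x[2,4] = f_LL`).
#'
#' @param tab Data frame with columns `age` and the ten schedule columns
#'   (see [species_schedule_table()]), one row per age class.
#' @return An `agestage_schedules` object with `s = 4`.
#' @export
schedules_from_table <- function(tab) {
  missing_cols <- setdiff(c("age", schedule_columns), names(tab))
  if (length(missing_cols)) {
    stop("schedule table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  omega <- nrow(tab)
  if (!isTRUE(all.equal(as.numeric(tab$age), as.numeric(seq_len(omega))))) {
    stop("schedule table must have one row per age class 1..omega, in order")
  }
  for (cl in schedule_columns) {
    v <- tab[[cl]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      stop("non-numeric value in schedule column '", cl, "'")
    }
    if (grepl("^sigma|^gamma", cl) && any(v < 0 | v > 1)) {
      bad <- which(v < 0 | v > 1)[1]
      stop("probability out of [0, 1] in column '", cl, "' at age ", bad)
    }
    if (grepl("^f_", cl) && any(v < 0)) {
      stop("negative fertility in column '", cl, "' at age ",
           which(v < 0)[1])
    }
  }
  U <- vector("list", omega)
  F <- vector("list", omega)
  for (x in seq_len(omega)) {
    r <- tab[x, ]
    Ux <- matrix(0, 4, 4)
    Ux[1, 1] <- r$sigma_JS * (1 - r$gamma_S)
    Ux[2, 2] <- r$sigma_JL * (1 - r$gamma_L)
    Ux[3, 1] <- r$sigma_JS * r$gamma_S
    Ux[4, 2] <- r$sigma_JL * r$gamma_L
    Ux[3, 3] <- r$sigma_AS
    Ux[4, 4] <- r$sigma_AL
    Fx <- matrix(0, 4, 4)
    Fx[1, 3] <- r$f_SS
    Fx[1, 4] <- r$f_LS
    Fx[2, 3] <- r$f_SL
    Fx[2, 4] <- r$f_LL
    U[[x]] <- Ux
    F[[x]] <- Fx
  }
  make_schedules(U = U, F = F)
}

#' @rdname schedules_from_table
#' @param config An `agestage_species_config`.
#' @export
build_example_schedules <- function(config = species_config()) {
  schedules_from_table(species_schedule_table(config))
}

#' Read and write age-schedule tables as CSV
#'
#' The CSV has a header row `age, sigma_JS, ..., f_LL` and one row per age
#' class; a writer/loader round trip reproduces the schedules exactly.
#' Validation (probabilities in `[0, 1]`, nonnegative fertilities, ordered
#' complete ages) happens on load.
#'
#' @param path CSV file path.
#' @return `load_schedule_table()` returns an `agestage_schedules` object;
#'   `write_schedule_table()` returns `path` invisibly.
#' @export
load_schedule_table <- function(path) {
  tab <- utils::read.csv(path)
  schedules_from_table(tab)
}

#' @rdname load_schedule_table
#' @param tab Schedule data frame.
#' @export
write_schedule_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Hand-checkable toy models
#'
#' Small models whose demographic quantities are known in closed form,
#' used throughout the test suite:
#' * `"T1"`: one stage, two age classes, survival 0.5 then 0, fertility
#'   `m` at age 2 (default `m = 2`). Two life paths: die at step 1 with
#'   probability 1/2, else at step 2. Survivorship (1, 0.5, 0); mean
#'   longevity at birth 1.5, variance 0.25; `R0 = m/2`;
#'   `lambda = sqrt(m/2)`; cohort generation time 1.
#' * `"T2"`: two stages, two age classes, no reproduction. Stage 1 dies
#'   during its first step (longevity 1); stage 2 survives exactly one
#'   step more (longevity 2). Under an equal mixture the variance in
#'   longevity is 0.25, all of it between-stage.
#' * `"T3"`: seeded random substochastic model (`s = 2`, `omega = 3`)
#'   with reproduction, for property-style tests.
#'
#' @param label `"T1"`, `"T2"`, or `"T3"`.
#' @param m Fertility of the second age class for `"T1"`.
#' @param seed Seed for `"T3"`.
#' @return List with `schedules` (an `agestage_schedules`), `model` (the
#'   assembled `agestage_model`), and `truths` (a list of closed-form
#'   values, where documented).
#' @export
toy_fixture <- function(label, m = 2, seed = 421) {
  if (label == "T1") {
    sch <- make_schedules(U = list(matrix(0.5), matrix(0)),
                          F = list(matrix(0), matrix(m)))
    truths <- list(lambda = sqrt(m / 2), R0 = m / 2,
                   eta1 = c(1.5, 1), var = c(0.25, 0),
                   ell = c(1, 0.5, 0), Gamma = 1,
                   N_fund = matrix(c(1, 0.5, 0, 1), 2, 2),
                   death_age_from_birth = c(0.5, 0.5),
                   eta_dagger_birth = 1.25)
  } else if (label == "T2") {
    U1 <- matrix(c(0, 0, 0, 1), 2, 2)    # stage 2 survives, stays stage 2
    U2 <- matrix(0, 2, 2)
    sch <- make_schedules(U = list(U1, U2),
                          F = list(matrix(0, 2, 2), matrix(0, 2, 2)))
    truths <- list(eta1_birth = c(1, 2), var_birth = c(0, 0),
                   v_within = 0, v_between = 0.25, v_total = 0.25,
                   pi = c(0.5, 0.5))
  } else if (label == "T3") {
    set.seed(seed)
    s <- 2; omega <- 3
    U <- replicate(omega, {
      M <- matrix(stats::runif(s * s), s, s)
      sweep(M, 2, colSums(M) / stats::runif(s, 0.5, 0.9), "/")
    }, simplify = FALSE)
    F <- replicate(omega, {
      M <- matrix(0, s, s)
      M[1, ] <- stats::runif(s, 0, 2)    # single offspring type
      M
    }, simplify = FALSE)
    sch <- make_schedules(U = U, F = F)
    truths <- list(seed = seed)
  } else {
    stop("unknown toy label: ", label)
  }
  list(schedules = sch, model = assemble_model(sch), truths = truths)
}

#' Individual-based Monte Carlo simulation of the mortality chain
#'
#' Simulates `n` independent individuals through the age x stage life
#' cycle defined by the schedules: each is born into age class 1 with a
#' stage drawn from `birth_pi`; at every step it survives and moves to a
#' destination joint state with the probabilities in the corresponding
#' column of the assembled transition matrix, or dies with the residual
#' probability, death being attributed to the state just occupied.
#' Offspring are accumulated as the expected per-step production of each
#' type (the per-capita semantics of the fertility matrices), or as
#' Poisson draws if `offspring = "poisson"`.
#'
#' The simulation is step-synchronous and vectorized over individuals
#' under a single seeded stream, so results are reproducible for a given
#' `(n, seed)` pair.
#'
#' @param schedules An `agestage_schedules` object.
#' @param n Number of individuals (>= 1).
#' @param seed Integer seed.
#' @param birth_pi Stage mixing distribution at birth.
#' @param offspring `"expected"` (default) or `"poisson"`.
#' @param max_steps Safety cap on the number of steps (an error past it
#'   indicates an effectively immortal schedule).
#' @return An object of class `agestage_microsim`: list with `n`, `seed`,
#'   `birth_stage` (integer vector), `longevity` (integer vector),
#'   `death_state` (joint index at death), `offspring` (`n x s` matrix of
#'   lifetime offspring by type), and `summary`, a per-birth-stage list
#'   with means, variances, death-age distributions, and standard errors.
#' @export
microsimulate <- function(schedules, n, seed, birth_pi,
                          offspring = c("expected", "poisson"),
                          max_steps = 100000L) {
  stopifnot(inherits(schedules, "agestage_schedules"), n >= 1)
  offspring <- match.arg(offspring)
  model <- assemble_model(schedules)
  s <- model$s; omega <- model$omega
  nstate <- s * omega
  rho <- max(Mod(eigen(model$U, only.values = TRUE)$values), 0)
  if (rho >= 1 - 1e-12) stop("immortal schedules: absorption is not certain")
  birth_pi <- as_mixing(birth_pi, s)
  # per-type offspring produced in one step from each joint state
  f_per_state <- model$F[seq_len(s), , drop = FALSE]  # (e1' (x) I_s) Ftilde
  death_p <- pmax(1 - colSums(model$U), 0)

  set.seed(seed)
  birth_stage <- sample.int(s, n, replace = TRUE, prob = birth_pi)
  state <- birth_stage                      # joint index of (age 1, stage)
  alive <- rep(TRUE, n)
  longevity <- integer(n)
  death_state <- integer(n)
  off <- matrix(0, n, s)
  step <- 0L
  while (any(alive)) {
    step <- step + 1L
    if (step > max_steps) stop("simulation exceeded max_steps; schedules nearly immortal")
    idx <- which(alive)
    longevity[idx] <- longevity[idx] + 1L
    if (offspring == "expected") {
      off[idx, ] <- off[idx, ] + t(f_per_state[, state[idx], drop = FALSE])
    } else {
      lam <- t(f_per_state[, state[idx], drop = FALSE])
      off[idx, ] <- off[idx, ] + matrix(stats::rpois(length(lam), lam),
                                        nrow = length(idx))
    }
    for (k in unique(state[idx])) {
      who <- idx[state[idx] == k]
      probs <- c(model$U[, k], death_p[k])
      dest <- sample.int(nstate + 1L, length(who), replace = TRUE, prob = probs)
      died <- dest == nstate + 1L
      death_state[who[died]] <- k
      alive[who[died]] <- FALSE
      state[who[!died]] <- dest[!died]
    }
  }

  per_stage <- lapply(seq_len(s), function(b) {
    sel <- birth_stage == b
    nb <- sum(sel)
    if (nb == 0) return(list(n = 0L))
    lv <- longevity[sel]
    dev2 <- (lv - mean(lv))^2
    death_age <- (death_state[sel] - 1L) %/% s + 1L
    p_age <- tabulate(death_age, nbins = omega) / nb
    list(n = nb,
         longevity_mean = mean(lv),
         longevity_mean_se = stats::sd(lv) / sqrt(nb),
         longevity_var = stats::var(lv),
         longevity_var_se = stats::sd(dev2) / sqrt(nb),
         offspring_mean = colMeans(off[sel, , drop = FALSE]),
         offspring_se = apply(off[sel, , drop = FALSE], 2, stats::sd) / sqrt(nb),
         death_age_dist = p_age,
         death_age_se = sqrt(p_age * (1 - p_age) / nb))
  })
  structure(
    list(n = n, seed = seed, birth_stage = birth_stage,
         longevity = longevity, death_state = death_state,
         offspring = off, summary = per_stage, s = s, omega = omega),
    class = "agestage_microsim"
  )
}
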