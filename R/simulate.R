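#' Simulation configuration for synthetic light-dark plates
#'
#' Describes a 96-well plate emulating the standard behavioral design: five
#' semi-log concentrations at n = 16 plus 16 vehicle wells, the 20/40/40-min
#' protocol at 2-min bins, right-skewed activity with a dark-startle burst
#' that habituates, and Hill-shaped concentration effects acting
#' multiplicatively on one or more activity drivers.
#'
#' Bin distances are Gamma-distributed around a per-phase mean curve scaled
#' by a per-larva log-normal frailty, giving the non-negative, right-skewed
#' activity distributions seen in real plates. The light phase has a low
#' mean with a mild within-phase trend; the dark phase is a plateau plus a
#' startle amplitude decaying exponentially with bin index (habituation).
#' Effects are Hill factors `1 - Emax * c^h / (c^h + AC50^h)` applied to a
#' driver: `light_level` and `dark_level` scale the whole phase mean,
#' `startle_amp` only the startle burst, `habituation_rate` the decay rate.
#'
#' @param concentrations Treated concentrations in uM (default the five
#'   highest of the 1-100 uM semi-log series).
#' @param n_per_conc,n_vehicle Larvae per treated group and vehicle group.
#' @param protocol An [assay_protocol()].
#' @param light_mean Light-phase mean activity, cm/bin.
#' @param light_slope Additive within-light trend, cm/bin per bin index.
#' @param dark_plateau Dark-phase plateau, cm/bin.
#' @param startle_amp Startle amplitude added to the first dark bin, cm/bin.
#' @param habituation_rate Exponential decay rate of the startle per bin.
#' @param acclimation_mean Acclimation-phase mean, cm/bin.
#' @param frailty_sd SD of the per-larva log-normal frailty (log scale).
#' @param gamma_shape Shape of the Gamma bin noise (smaller = more skewed).
#' @param effects List of effects, each `list(driver =, emax =, ac50 =,
#'   hill =)` with `driver` one of `"light_level"`, `"dark_level"`,
#'   `"startle_amp"`, `"habituation_rate"`, `emax` in `[0, 1]`.
#' @param devtox Named list of per-status logistic dose-response parameters,
#'   each `list(ec50 =, hill =, max =)` giving
#'   `P = max / (1 + (ec50/c)^hill)`, for statuses `dead`, `not_hatched`,
#'   `severe`, `abnormal`. `ec50 = Inf` disables a status.
#' @param chemical Chemical label carried through the tables.
#' @return A `zf_sim_config` list.
#' @export
sim_config <- function(concentrations = 100 * 10^(-0.5 * (4:0)),
                       n_per_conc = 16, n_vehicle = 16,
                       protocol = assay_protocol(),
                       light_mean = 3, light_slope = -0.02,
                       dark_plateau = 8, startle_amp = 6,
                       habituation_rate = 0.15,
                       acclimation_mean = 6,
                       frailty_sd = 0.3, gamma_shape = 5,
                       effects = list(),
                       devtox = list(),
                       chemical = "test_chemical") {
  stopifnot(
    all(concentrations > 0), n_per_conc >= 1, n_vehicle >= 1,
    light_mean >= 0, dark_plateau >= 0, startle_amp >= 0,
    habituation_rate >= 0, acclimation_mean >= 0,
    frailty_sd >= 0, gamma_shape > 0
  )
  drivers <- c("light_level", "dark_level", "startle_amp", "habituation_rate")
  for (ef in effects) {
    stopifnot(
      ef$driver %in% drivers,
      ef$emax >= 0, ef$emax <= 1, ef$ac50 > 0, ef$hill > 0
    )
  }
  statuses <- c("dead", "not_hatched", "severe", "abnormal")
  devtox_full <- setNames(
    lapply(statuses, function(s) {
      devtox[[s]] %||% list(ec50 = Inf, hill = 2, max = 1)
    }),
    statuses
  )
  structure(
    list(
      concentrations = sort(concentrations), n_per_conc = n_per_conc,
      n_vehicle = n_vehicle, protocol = protocol,
      light_mean = light_mean, light_slope = light_slope,
      dark_plateau = dark_plateau, startle_amp = startle_amp,
      habituation_rate = habituation_rate,
      acclimation_mean = acclimation_mean,
      frailty_sd = frailty_sd, gamma_shape = gamma_shape,
      effects = effects, devtox = devtox_full, chemical = chemical
    ),
    class = "zf_sim_config"
  )
}

hill_factor <- function(emax, ac50, hill, conc) {
  if (conc <= 0) return(1)
  1 - emax * conc^hill / (conc^hill + ac50^hill)
}

# driver values after applying the Hill effects at a concentration
effective_drivers <- function(config, conc) {
  drv <- list(
    light_level = 1, dark_level = 1, startle_amp = config$startle_amp,
    habituation_rate = config$habituation_rate
  )
  for (ef in config$effects) {
    fac <- hill_factor(ef$emax, ef$ac50, ef$hill, conc)
    drv[[ef$driver]] <- drv[[ef$driver]] * fac
  }
  drv
}

# noiseless per-bin mean profile (frailty = 1) at a concentration
mean_profile <- function(config, conc) {
  p <- config$protocol
  drv <- effective_drivers(config, conc)
  acc <- rep(config$acclimation_mean, p$n_acclimation)
  j_l <- seq_len(p$n_light) - 1
  light <- pmax(config$light_mean + config$light_slope * j_l, 0.05) *
    drv$light_level
  j_d <- seq_len(p$n_dark) - 1
  dark <- (config$dark_plateau +
    drv$startle_amp * exp(-drv$habituation_rate * j_d)) * drv$dark_level
  list(acclimation = acc, light = light, dark = dark)
}

#' Simulate one larva's locomotor profile
#'
#' Draws a phase-labelled binned trace for one larva at a concentration:
#' a per-larva log-normal frailty (mean 1) scales the noiseless mean
#' profile, and each bin distance is Gamma-distributed with that mean and
#' the configured shape. Deterministic under a fixed seed.
#'
#' @param config A [sim_config()].
#' @param concentration Concentration in uM (>= 0; 0 for vehicle).
#' @param larva_id Identifier carried into the table.
#' @param seed Optional integer seed.
#' @return Bin tibble: `larva_id`, `chemical`, `conc_uM`, `bin_start_min`,
#'   `phase`, `distance_cm`.
#' @export
simulate_larva <- function(config, concentration, larva_id = "larva1",
                           seed = NULL) {
  stopifnot(inherits(config, "zf_sim_config"))
  if (!is.numeric(concentration) || concentration < 0) {
    abort("concentration must be >= 0")
  }
  draw <- function() {
    p <- config$protocol
    mu <- mean_profile(config, concentration)
    frailty <- exp(rnorm(1, -config$frailty_sd^2 / 2, config$frailty_sd))
    mu_all <- c(mu$acclimation, mu$light, mu$dark) * frailty
    k <- config$gamma_shape
    dist <- rgamma(length(mu_all), shape = k, rate = k / pmax(mu_all, 1e-9))
    tibble(
      larva_id = larva_id,
      chemical = if (concentration > 0) config$chemical else "vehicle",
      conc_uM = concentration,
      bin_start_min = p$bin_min * (seq_along(mu_all) - 1),
      phase = rep(phase_levels, c(p$n_acclimation, p$n_light, p$n_dark)),
      distance_cm = dist
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

status_prob <- function(par, conc) {
  if (!is.finite(par$ec50)) return(0)
  if (conc <= 0) return(0)
  par$max / (1 + (par$ec50 / conc)^par$hill)
}

#' Simulate a full 96-well plate
#'
#' Randomly assigns the treated groups and vehicle controls to wells, draws
#' developmental-toxicity observations from the configured logistic
#' dose-response models (in precedence order dead, then not hatched, then
#' severe, then mild abnormality), and generates locomotor profiles for the
#' larvae that pass the behavior-inclusion filter (live, hatched,
#' morphologically normal). Identical config + seed reproduce identical
#' tables.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param plate_id Plate identifier.
#' @return A `zf_plate` list: `bins` (profiles of included larvae),
#'   `plate_map` (well to treatment), `observations` (well-level raw
#'   observations with status), and `truth` (ground-truth effect table).
#' @export
simulate_plate <- function(config, seed = 1, plate_id = "plate1") {
  stopifnot(inherits(config, "zf_sim_config"))
  n_total <- config$n_per_conc * length(config$concentrations) + config$n_vehicle
  wells_all <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, times = 8))
  if (n_total > length(wells_all)) abort("layout overflow: > 96 wells requested")
  withr::with_seed(seed, {
    conc_vec <- c(
      rep(config$concentrations, each = config$n_per_conc),
      rep(0, config$n_vehicle)
    )
    wells <- sample(wells_all, n_total)
    plate_map <- tibble(
      plate_id = plate_id, well = wells,
      chemical = ifelse(conc_vec > 0, config$chemical, "vehicle"),
      conc_uM = conc_vec
    ) %>% arrange(.data$well)

    obs <- plate_map %>% mutate(
      larva_id = paste0(plate_id, "_", .data$well),
      p_dead = vapply(.data$conc_uM, function(c) status_prob(config$devtox$dead, c), 1),
      p_nh = vapply(.data$conc_uM, function(c) status_prob(config$devtox$not_hatched, c), 1),
      p_sev = vapply(.data$conc_uM, function(c) status_prob(config$devtox$severe, c), 1),
      p_abn = vapply(.data$conc_uM, function(c) status_prob(config$devtox$abnormal, c), 1),
      dead = runif(n()) < .data$p_dead,
      unhatched = runif(n()) < .data$p_nh,
      severe = runif(n()) < .data$p_sev,
      mild = runif(n()) < .data$p_abn,
      alive = !.data$dead,
      hatched = !.data$unhatched,
      malformations = dplyr::case_when(
        .data$severe ~ "spinal;craniofacial",
        .data$mild ~ "swim_bladder_not_inflated",
        TRUE ~ ""
      ),
      severity = dplyr::case_when(
        .data$severe ~ "severe",
        .data$mild ~ "mild",
        TRUE ~ "none"
      )
    ) %>%
      select("plate_id", "well", "larva_id", "chemical", "conc_uM",
             "alive", "hatched", "malformations", "severity") %>%
      classify_status() %>%
      behavior_inclusion()

    included <- obs %>% filter(.data$include)
    bins <- purrr::map_dfr(seq_len(nrow(included)), function(i) {
      simulate_larva(config, included$conc_uM[i],
                     larva_id = included$larva_id[i]) %>%
        mutate(plate_id = plate_id, well = included$well[i], .before = 1)
    })

    truth <- tibble(
      chemical = config$chemical,
      active = length(config$effects) > 0 &&
        any(vapply(config$effects, function(e) e$emax > 0, logical(1))),
      drivers = list(config$effects)
    )
    structure(
      list(bins = bins, plate_map = plate_map, observations = obs,
           truth = truth, config = config, seed = seed),
      class = "zf_plate"
    )
  })
}

#' @export
print.zf_plate <- function(x, ...) {
  cat(sprintf(
    "<zf_plate> %s: %d wells, %d larvae with profiles, chemical %s (seed %s)\n",
    x$plate_map$plate_id[1], nrow(x$plate_map),
    length(unique(x$bins$larva_id)), x$config$chemical, format(x$seed)
  ))
  invisible(x)
}

#' Ground-truth benchmark concentration by noiseless forward evaluation
#'
#' Evaluates the configured effect model with no noise (frailty 1, Gamma
#' mean), computes the endpoint value as a deterministic function of
#' concentration, standardizes the shift from the vehicle value with the
#' supplied reference, and solves `|standardized shift| = BMR` by grid
#' bracketing plus bisection. This is the oracle against which pipeline BMC
#' estimates are judged in recovery tests.
#'
#' @param config A [sim_config()] with at least one effect.
#' @param endpoint One of [endpoint_names()].
#' @param reference A fitted [fit_vehicle_reference()] for standardization.
#' @param bmr BMR in control-SD units (default 1.349).
#' @param conc_range Search range in uM (default spans the tested series).
#' @return The true BMC in uM, or `NA` when the endpoint never reaches the
#'   BMR in range.
#' @export
true_bmc <- function(config, endpoint, reference, bmr = 1.349,
                     conc_range = NULL) {
  stopifnot(inherits(config, "zf_sim_config"),
            inherits(reference, "vehicle_reference"))
  if (!length(config$effects)) return(NA_real_)
  if (!endpoint %in% endpoint_names()) abort("unknown endpoint")
  row <- reference[reference$endpoint == endpoint, ]
  std <- function(conc) {
    mu <- mean_profile(config, conc)
    e <- endpoints_one(mu$light, mu$dark)[[endpoint]]
    (boxcox_transform(max(e + row$shift, eps_pos), row$lambda) - row$center) /
      row$scale
  }
  r0 <- std(0)
  g <- function(conc) abs(std(conc) - r0) - bmr
  rng <- conc_range %||%
    c(min(config$concentrations) / 100, max(config$concentrations))
  grid <- exp(seq(log(rng[1]), log(rng[2]), length.out = 400))
  vals <- vapply(grid, g, numeric(1))
  if (all(vals < 0)) return(NA_real_)
  i <- which(vals >= 0)[1]
  if (i == 1) return(grid[1])
  lo <- grid[i - 1]; hi <- grid[i]
  for (iter in 1:200) {
    mid <- sqrt(lo * hi)
    if (g(mid) >= 0) hi <- mid else lo <- mid
    if (abs(g(sqrt(lo * hi))) < 1e-8) break
  }
  sqrt(lo * hi)
}

#' Simulate a pooled vehicle-control reference
#'
#' Simulates a pool of vehicle-control larvae under the configuration's
#' baseline (no effects) and fits the per-endpoint Box-Cox reference on
#' them — the in-silico analogue of fitting the reference on a large
#' historical control set (the design this pipeline assumes: the reference
#' is fit once on a designated control pool and frozen). The default pool
#' size matches the 641-larva historical pool of the assay this package
#' models.
#'
#' @param config A [sim_config()].
#' @param n_controls Number of vehicle larvae to simulate (default 641).
#' @param seed Integer seed.
#' @param cutoff_multiplier Response cutoff in control-SD units.
#' @return A fitted [fit_vehicle_reference()].
#' @export
simulate_vehicle_reference <- function(config, n_controls = 641, seed = 1,
                                       cutoff_multiplier = 1) {
  stopifnot(inherits(config, "zf_sim_config"))
  bins <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_controls), function(i) {
      simulate_larva(config, 0, larva_id = sprintf("ctrl_%04d", i))
    })
  })
  fit_vehicle_reference(compute_endpoints(bins),
                        cutoff_multiplier = cutoff_multiplier)
}
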