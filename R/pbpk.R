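# Minimal mass-balanced compartmental pharmacokinetic simulator for the
# hepatic isoniazid cascade. This is deliberately a 4-compartment toy
# (gut lumen, central/plasma, liver intracellular, urine sink), not a
# whole-body PBPK re-implementation: the coupling layer only needs the
# time-resolved intracellular liver reaction rates and a closed mass
# balance. Hepatic reactions follow Michaelis-Menten kinetics, absorption
# and renal elimination are first order, hepatic distribution is
# flow-limited. Amounts in umol, rates in umol liver^-1 min^-1.

PBPK_SPECIES <- c("INH", "ACINH", "INA", "INGLY", "HZ", "ACHZ", "DIACHZ")
PBPK_REACTIONS <- c("NAT2_INH", "AMID_INH", "AMID_ACINH", "GLYAT_INA",
                    "NAT2_HZ", "NAT2_ACHZ", "CYP2E1_ACHZ", "NOS2_HZ")

#' Construct a toy pharmacokinetic model of the isoniazid cascade
#'
#' Species: isoniazid (INH), acetylisoniazid (ACINH), isonicotinic acid
#' (INA), isonicotinoyl glycine (INGLY), hydrazine (HZ), acetylhydrazine
#' (ACHZ), diacetylhydrazine (DIACHZ). Hepatic reactions: NAT2 acetylation
#' of INH/HZ/ACHZ, amidase hydrolysis of INH and ACINH, glycine
#' conjugation of INA, CYP2E1 oxidation of ACHZ and NOS2-mediated HZ
#' clearance. Every species carries one isonicotinyl and/or one hydrazine
#' moiety, so moiety-wise mass balance is closed by construction:
#' amounts in all compartments plus cumulative urinary excretion and
#' oxidative sinks always sum to the administered dose.
#'
#' @param volumes list with `plasma` and `liver` volumes (L).
#' @param ka first-order absorption rate constant (min^-1).
#' @param q_hepatic plasma-liver transfer clearance (L min^-1), applied to
#'   every species.
#' @param cl_extrahepatic first-order extrahepatic hydrolysis clearance of
#'   plasma INH to INA (L min^-1); represents non-NAT2 elimination outside
#'   the liver.
#' @param enzymes data frame with columns `reaction`, `vmax`
#'   (umol min^-1), `km` (uM) and `nat2` (logical: scaled by the
#'   acetylator phenotype).
#' @param renal named vector of first-order renal clearances per species
#'   (L min^-1).
#' @param doses data frame with columns `time` (min) and `amount` (umol);
#'   oral route, into the gut compartment.
#' @param phenotype list with `label` (`"fast"`/`"slow"`) and
#'   `nat2_vmax_scale` (multiplier on all NAT2-catalyzed Vmax values).
#' @return object of class `toy_pbpk_model`.
#' @seealso [acetylator_preset()], [simulate_pbpk()], [multi_dose()]
#' @export
toy_pbpk_model <- function(volumes, ka, q_hepatic, cl_extrahepatic,
                           enzymes, renal, doses, phenotype) {
  stopifnot(volumes$plasma > 0, volumes$liver > 0, ka > 0, q_hepatic > 0)
  enzymes <- as.data.frame(enzymes)
  if (!setequal(enzymes$reaction, PBPK_REACTIONS))
    dmoma_stop("dmoma_validation_error", paste0(
      "enzymes must cover exactly the reactions: ",
      paste(PBPK_REACTIONS, collapse = ", ")))
  if (any(enzymes$vmax <= 0) || any(enzymes$km <= 0))
    dmoma_stop("dmoma_validation_error", "Vmax and Km must be positive")
  if (!setequal(names(renal), PBPK_SPECIES))
    dmoma_stop("dmoma_validation_error",
               "renal clearances must cover every species")
  if (phenotype$nat2_vmax_scale <= 0)
    dmoma_stop("dmoma_validation_error", "nat2_vmax_scale must be positive")
  structure(list(volumes = volumes, ka = ka, q_hepatic = q_hepatic,
                 cl_extrahepatic = cl_extrahepatic,
                 enzymes = enzymes[match(PBPK_REACTIONS, enzymes$reaction), ],
                 renal = renal[PBPK_SPECIES],
                 doses = as.data.frame(doses),
                 phenotype = phenotype,
                 species = PBPK_SPECIES),
            class = "toy_pbpk_model")
}

#' NAT2 acetylator phenotype presets
#'
#' Fast and slow acetylator parameterizations of the toy isoniazid model.
#' The two presets are identical except for the NAT2 Vmax scale, which
#' multiplies all NAT2-catalyzed reactions. The parameters are fixture
#' constants chosen so that, for a single 300 mg oral dose, the fast
#' phenotype metabolizes roughly two-thirds of the dose in the liver, the
#' slow phenotype well under a quarter, and the slow phenotype excretes
#' about half of the dose as unchanged drug in urine.
#'
#' @param label `"fast"` or `"slow"`.
#' @param dose_umol administered dose in umol (default 2187.5, i.e.
#'   300 mg isoniazid at 137.14 g/mol).
#' @return a [toy_pbpk_model()].
#' @export
acetylator_preset <- function(label = c("fast", "slow"),
                              dose_umol = 2187.5) {
  label <- match.arg(label)
  enzymes <- data.frame(
    reaction = PBPK_REACTIONS,
    vmax = c(75, 2, 10, 2.5, 12, 15, 2, 1.5),
    km = c(200, 200, 150, 100, 100, 100, 150, 100),
    nat2 = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE))
  renal <- c(INH = 0.10, ACINH = 0.12, INA = 0.18, INGLY = 0.25,
             HZ = 0.02, ACHZ = 0.04, DIACHZ = 0.18)
  toy_pbpk_model(
    volumes = list(plasma = 40, liver = 1.5),
    ka = 0.05, q_hepatic = 1.2, cl_extrahepatic = 0.055,
    enzymes = enzymes, renal = renal,
    doses = data.frame(time = 0, amount = dose_umol),
    phenotype = list(label = label,
                     nat2_vmax_scale = if (label == "fast") 1 else 0.07))
}

#' Append repeated dosing events
#'
#' @param model a `toy_pbpk_model` (its first dose defines amount/offset).
#' @param n_doses total number of doses (>= 1).
#' @param interval time between doses (min, > 0).
#' @return the model with `n_doses` dosing events at `interval` spacing.
#' @export
multi_dose <- function(model, n_doses, interval) {
  stopifnot(inherits(model, "toy_pbpk_model"))
  if (n_doses < 1) dmoma_stop("dmoma_validation_error", "n_doses must be >= 1")
  if (n_doses > 1 && interval <= 0)
    dmoma_stop("dmoma_validation_error", "dose interval must be positive")
  base <- model$doses[1, ]
  model$doses <- data.frame(
    time = base$time + interval * (seq_len(n_doses) - 1),
    amount = base$amount)
  model
}

#' Simulate the toy pharmacokinetic model
#'
#' Integrates the compartmental ODE system with an adaptive stiff solver
#' (`deSolve::lsoda`, absolute tolerance 1e-10 umol) and samples the
#' hepatic intracellular reaction rates on a uniform `dt` grid.
#'
#' @param model a [toy_pbpk_model()].
#' @param duration total simulated time (min, default 4320 = 72 h); must
#'   cover all dosing events.
#' @param dt output step (min, default 1); must divide `duration`.
#' @return list with:
#'   \describe{
#'     \item{rates}{a [rate_time_series()] of the 8 hepatic xenobiotic
#'       reaction rates (umol liver^-1 min^-1).}
#'     \item{amounts}{data frame of all state trajectories (umol).}
#'     \item{ledger}{excretion/mass-balance ledger: per-species urinary
#'       fractions of dose, net hepatic uptake (+) / secretion (-)
#'       fractions, oxidative sink fractions, the isonicotinyl and
#'       hydrazine moiety recoveries, and the administered dose.}
#'   }
#' @export
simulate_pbpk <- function(model, duration = 4320, dt = 1) {
  stopifnot(inherits(model, "toy_pbpk_model"))
  if (duration <= 0 || dt <= 0 || abs(duration / dt - round(duration / dt)) > 1e-9)
    dmoma_stop("dmoma_validation_error", "dt must divide duration")
  if (any(model$doses$time > duration))
    dmoma_stop("dmoma_validation_error",
               "duration does not cover all dosing events")

  sp <- PBPK_SPECIES; rx <- PBPK_REACTIONS
  vmax <- stats::setNames(model$enzymes$vmax, model$enzymes$reaction)
  km <- stats::setNames(model$enzymes$km, model$enzymes$reaction)
  scale <- ifelse(model$enzymes$nat2, model$phenotype$nat2_vmax_scale, 1)
  vmax <- vmax * stats::setNames(scale, model$enzymes$reaction)
  Vp <- model$volumes$plasma; Vl <- model$volumes$liver
  Q <- model$q_hepatic; CLx <- model$cl_extrahepatic
  renal <- model$renal

  y0 <- stats::setNames(
    numeric(1 + 3 * length(sp) + length(rx) + length(sp)),
    c("gut", paste0("P_", sp), paste0("L_", sp), paste0("U_", sp),
      paste0("CUM_", rx), paste0("NETQ_", sp)))

  mm_rates <- function(Cl) {
    c(NAT2_INH    = vmax[["NAT2_INH"]] * Cl[["INH"]] / (km[["NAT2_INH"]] + Cl[["INH"]]),
      AMID_INH    = vmax[["AMID_INH"]] * Cl[["INH"]] / (km[["AMID_INH"]] + Cl[["INH"]]),
      AMID_ACINH  = vmax[["AMID_ACINH"]] * Cl[["ACINH"]] / (km[["AMID_ACINH"]] + Cl[["ACINH"]]),
      GLYAT_INA   = vmax[["GLYAT_INA"]] * Cl[["INA"]] / (km[["GLYAT_INA"]] + Cl[["INA"]]),
      NAT2_HZ     = vmax[["NAT2_HZ"]] * Cl[["HZ"]] / (km[["NAT2_HZ"]] + Cl[["HZ"]]),
      NAT2_ACHZ   = vmax[["NAT2_ACHZ"]] * Cl[["ACHZ"]] / (km[["NAT2_ACHZ"]] + Cl[["ACHZ"]]),
      CYP2E1_ACHZ = vmax[["CYP2E1_ACHZ"]] * Cl[["ACHZ"]] / (km[["CYP2E1_ACHZ"]] + Cl[["ACHZ"]]),
      NOS2_HZ     = vmax[["NOS2_HZ"]] * Cl[["HZ"]] / (km[["NOS2_HZ"]] + Cl[["HZ"]]))
  }

  deriv <- function(t, y, parms) {
    Cp <- stats::setNames(y[paste0("P_", sp)] / Vp, sp)
    Cl <- stats::setNames(pmax(y[paste0("L_", sp)], 0) / Vl, sp)
    v <- mm_rates(Cl)
    tr <- Q * (Cp - Cl)          # plasma -> liver net transfer, umol/min
    abs_in <- model$ka * y[["gut"]]

    dP <- -tr - renal[sp] * Cp[sp]
    dP[["INH"]] <- dP[["INH"]] + abs_in - CLx * Cp[["INH"]]
    dP[["INA"]] <- dP[["INA"]] + CLx * Cp[["INH"]]
    dP[["HZ"]] <- dP[["HZ"]] + CLx * Cp[["INH"]]   # moiety liberated too

    dL <- tr
    dL[["INH"]]    <- dL[["INH"]] - v[["NAT2_INH"]] - v[["AMID_INH"]]
    dL[["ACINH"]]  <- dL[["ACINH"]] + v[["NAT2_INH"]] - v[["AMID_ACINH"]]
    dL[["INA"]]    <- dL[["INA"]] + v[["AMID_INH"]] + v[["AMID_ACINH"]] -
                        v[["GLYAT_INA"]]
    dL[["INGLY"]]  <- dL[["INGLY"]] + v[["GLYAT_INA"]]
    dL[["HZ"]]     <- dL[["HZ"]] + v[["AMID_INH"]] - v[["NAT2_HZ"]] -
                        v[["NOS2_HZ"]]
    dL[["ACHZ"]]   <- dL[["ACHZ"]] + v[["AMID_ACINH"]] + v[["NAT2_HZ"]] -
                        v[["NAT2_ACHZ"]] - v[["CYP2E1_ACHZ"]]
    dL[["DIACHZ"]] <- dL[["DIACHZ"]] + v[["NAT2_ACHZ"]]

    dU <- renal[sp] * Cp[sp]
    list(c(-abs_in, dP, dL, dU, v, tr))
  }

  times <- seq(0, duration, by = dt)
  ev_times <- model$doses$time
  events <- data.frame(var = "gut", time = ev_times,
                       value = model$doses$amount, method = "add")
  # an event exactly at t = 0 is folded into the initial condition
  at0 <- events$time <= 0
  if (any(at0)) {
    y0[["gut"]] <- sum(events$value[at0])
    events <- events[!at0, ]
  }
  ev_arg <- if (nrow(events)) list(data = events) else NULL
  sol <- deSolve::lsoda(y0, times, deriv, parms = NULL,
                        atol = 1e-10, rtol = 1e-8, events = ev_arg)
  if (attr(sol, "istate")[1] < 0)
    dmoma_stop("dmoma_solver_error", paste0(
      "ODE integration failed (istate = ", attr(sol, "istate")[1],
      "); try a smaller dt or looser tolerances"))
  sol <- as.data.frame(sol)

  Clm <- as.matrix(sol[paste0("L_", sp)]) / Vl
  colnames(Clm) <- sp
  rates <- t(apply(Clm, 1, function(row) mm_rates(as.list(row))))
  colnames(rates) <- rx
  series <- rate_time_series(times = sol$time, rates = rates)

  dose_total <- sum(model$doses$amount)
  final <- sol[nrow(sol), ]
  amount_of <- function(prefix) {
    vapply(sp, function(s) final[[paste0(prefix, s)]], numeric(1))
  }
  urinary <- amount_of("U_")
  body <- amount_of("P_") + amount_of("L_")
  body[["INH"]] <- body[["INH"]] + final$gut
  sink_cyp <- final$CUM_CYP2E1_ACHZ
  sink_nos <- final$CUM_NOS2_HZ
  iso_sp <- c("INH", "ACINH", "INA", "INGLY")
  hz_sp <- c("INH", "ACINH", "HZ", "ACHZ", "DIACHZ")
  ledger <- list(
    dose_umol = dose_total,
    urinary_fraction = urinary / dose_total,
    body_residual_fraction = body / dose_total,
    hepatic_net_uptake_fraction = amount_of("NETQ_") / dose_total,
    hepatic_reaction_umol = stats::setNames(
      vapply(rx, function(r) final[[paste0("CUM_", r)]], numeric(1)), rx),
    sink_fraction = c(CYP2E1_ACHZ = sink_cyp, NOS2_HZ = sink_nos) / dose_total,
    isonicotinyl_recovery = sum(urinary[iso_sp] + body[iso_sp]) / dose_total,
    hydrazinyl_recovery = (sum(urinary[hz_sp] + body[hz_sp]) +
                             sink_cyp + sink_nos) / dose_total,
    hepatic_metabolized_fraction =
      (final$CUM_NAT2_INH + final$CUM_AMID_INH) / dose_total)
  list(rates = series, amounts = sol, ledger = ledger)
}

#' Construct a time series of xenobiotic reaction rates
#'
#' @param times uniform time grid in minutes starting at 0.
#' @param rates numeric matrix, timepoints x reactions, with column names
#'   matching xenobiotic reaction ids; umol liver^-1 min^-1.
#' @return object of class `rate_time_series`.
#' @export
rate_time_series <- function(times, rates) {
  rates <- as.matrix(rates)
  if (length(times) != nrow(rates))
    dmoma_stop("dmoma_validation_error", "times and rates rows differ")
  if (length(times) < 2)
    dmoma_stop("dmoma_validation_error",
               "a rate series needs at least two timepoints to integrate")
  if (anyDuplicated(times))
    dmoma_stop("dmoma_validation_error", "duplicated timepoints")
  dts <- diff(times)
  if (any(abs(dts - dts[1]) > 1e-9 * max(1, dts[1])))
    dmoma_stop("dmoma_validation_error",
               "non-uniform time grid: resample first")
  if (anyNA(rates))
    dmoma_stop("dmoma_validation_error", "NaN/NA rate values")
  if (is.null(colnames(rates)) || anyDuplicated(colnames(rates)))
    dmoma_stop("dmoma_validation_error",
               "rates need unique reaction-id column names")
  rates[abs(rates) < 1e-12] <- 0   # zap integrator noise
  if (any(rates < 0))
    dmoma_stop("dmoma_validation_error", paste0(
      "negative rate for irreversible reaction(s): ",
      paste(colnames(rates)[apply(rates < 0, 2, any)], collapse = ", ")))
  structure(list(times = as.numeric(times), rates = rates,
                 dt = as.numeric(dts[1])),
            class = "rate_time_series")
}

#' Read a rate table from CSV
#'
#' Expects a `time_min` column plus one column per xenobiotic reaction id
#' (umol liver^-1 min^-1), on a uniform time grid.
#'
#' @param path CSV file path.
#' @return a [rate_time_series()].
#' @export
read_rate_table <- function(path) {
  tab <- read_delim_sniff(path)
  if (!"time_min" %in% names(tab))
    dmoma_stop("dmoma_format_error", "rate table lacks a 'time_min' column")
  rates <- as.matrix(tab[setdiff(names(tab), "time_min")])
  if (anyNA(rates)) {
    bad <- which(is.na(rates), arr.ind = TRUE)[1, ]
    dmoma_stop("dmoma_format_error", paste0(
      "NaN rate at row ", bad[1], ", column '", colnames(rates)[bad[2]], "'"))
  }
  if (any(rates < 0)) {
    bad <- which(rates < 0, arr.ind = TRUE)[1, ]
    dmoma_stop("dmoma_format_error", paste0(
      "negative rate at row ", bad[1], ", column '",
      colnames(rates)[bad[2]], "'"))
  }
  rate_time_series(times = tab$time_min, rates = rates)
}

#' Write a rate table to CSV
#' @param series a `rate_time_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(series, path) {
  tab <- data.frame(time_min = series$times, series$rates,
                    check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Resample a rate series to a coarser uniform grid
#'
#' Mean-over-interval resampling: the coarse rate on each interval is the
#' mean of the fine rates it covers, so the time integral of every column
#' (under the left-rectangle rule used throughout the coupling) is
#' preserved exactly.
#'
#' @param series a `rate_time_series`.
#' @param dt target step; must be a positive multiple of the native step.
#' @return the resampled `rate_time_series`.
#' @export
resample_rates <- function(series, dt) {
  stopifnot(inherits(series, "rate_time_series"))
  f <- dt / series$dt
  if (f < 1 - 1e-9 || abs(f - round(f)) > 1e-9)
    dmoma_stop("dmoma_validation_error",
               "dt must be a positive integer multiple of the native step")
  f <- round(f)
  if (f == 1L) return(series)
  n_int <- nrow(series$rates) - 1L
  n_grp <- n_int %/% f
  if (n_grp < 1)
    dmoma_stop("dmoma_validation_error", "series too short for this dt")
  grp <- rep(seq_len(n_grp), each = f)
  used <- seq_len(n_grp * f)
  coarse <- apply(series$rates[used, , drop = FALSE], 2,
                  function(col) tapply(col, grp, mean))
  coarse <- rbind(coarse, series$rates[n_grp * f + 1L, ])
  rate_time_series(times = seq(0, by = dt, length.out = n_grp + 1L) +
                     series$times[1],
                   rates = coarse)
}

#' @export
print.toy_pbpk_model <- function(x, ...) {
  cat("toy_pbpk_model (", x$phenotype$label, " acetylator, NAT2 scale ",
      x$phenotype$nat2_vmax_scale, "): ", nrow(x$doses), " dose(s) of ",
      x$doses$amount[1], " umol\n", sep = "")
  invisible(x)
}

#' @export
print.rate_time_series <- function(x, ...) {
  cat("rate_time_series: ", length(x$times), " timepoints (dt = ", x$dt,
      " min), reactions: ", paste(colnames(x$rates), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
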