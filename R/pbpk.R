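# Generation-resolved lung PBPK of an inhaled compound.
#
# Units used throughout: amounts nmol, volumes mL, time h, concentrations
# uM (= nmol/mL), permeability cm/s, diffusivity cm^2/s, lengths cm unless
# a field name says otherwise. The airway tree has 24 generations
# (1 = trachea; 1-16 tracheobronchial, 17-24 alveolar); each generation has
# an epithelial-lining-fluid (ELF), epithelium and sub-epithelium
# compartment, the epithelium and sub-epithelium each carrying a volume-less
# "deep" binding compartment. Undissolved particle mass in the ELF dissolves
# by the Nernst-Brunner law; the mucociliary escalator moves dissolved and
# solid ELF content one generation up (trachea -> swallowed sink, removed);
# the sub-epithelium exchanges with a one-compartment systemic circulation
# (CL, Vss) by perfusion-limited transport.

#' Default airway morphometry table
#'
#' Scalable Weibel-like dichotomous tree: generation g has 2^(g-1) airways
#' whose diameter and length shrink geometrically; surface area is the
#' cylinder area, compartment volumes are surface area times a thinning
#' layer thickness, and the mucociliary first-order rate is the mucus
#' velocity over the generation length (zero in the alveolar region).
#' Alveolar surface area vastly exceeds tracheobronchial surface area.
#' All values are defaults meant to be overridden with measured morphometry
#' where available.
#'
#' @return data.frame, one row per generation 1..24: `generation`, `region`
#'   ("tracheobronchial"/"alveolar"), `surface_area_cm2`, `elf_volume_ml`,
#'   `epithelium_volume_ml`, `subepithelium_volume_ml`,
#'   `mucociliary_rate_per_h`
#' @export
default_airway_morphometry <- function() {
  g <- 1:24
  tb <- g <= 16
  n_air <- 2^(g - 1)
  d_cm <- 1.8 * 0.83^(g - 1)
  l_cm <- 12 * 0.75^(g - 1)
  sa <- ifelse(tb, n_air * pi * d_cm * l_cm, 3400 * 2^(g - 17))
  elf_um <- ifelse(tb, 10 * 0.85^(g - 1), 0.07)
  epi_um <- ifelse(tb, 55 * 0.85^(g - 1), 0.2)
  sub_um <- epi_um
  v_mucus_mm_min <- ifelse(tb, 5.5 * 0.7^(g - 1), 0)
  mc_rate <- ifelse(tb, v_mucus_mm_min / (l_cm * 10) * 60, 0)
  data.frame(
    generation = g,
    region = ifelse(tb, "tracheobronchial", "alveolar"),
    surface_area_cm2 = sa,
    elf_volume_ml = sa * elf_um * 1e-4,
    epithelium_volume_ml = sa * epi_um * 1e-4,
    subepithelium_volume_ml = sa * sub_um * 1e-4,
    mucociliary_rate_per_h = mc_rate)
}

#' Compound parameter set for the lung model
#'
#' @param solubility_cs_um aqueous solubility in the ELF (uM)
#' @param diffusion_cm2_s diffusion coefficient in the dissolution boundary
#'   layer
#' @param diffusion_layer_cm boundary-layer thickness of the
#'   Nernst-Brunner law
#' @param density_g_ml particle density
#' @param initial_radius_um initial radius of the monodisperse particles
#' @param permeability_tb_cm_s epithelial permeability in the
#'   tracheobronchial region
#' @param alveolar_permeability_multiplier alveolar permeability is this
#'   multiple of the tracheobronchial value (default 10)
#' @param fu_plasma,fu_tissue unbound fractions in (0, 1]
#' @param kp_epithelium,kp_subepithelium tissue:plasma partition
#'   coefficients (total basis)
#' @param k_in_per_h,k_out_per_h exchange rates with the volume-less deep
#'   binding compartment of each tissue
#' @param cl_ml_h systemic clearance
#' @param vss_ml systemic volume of distribution
#' @param mw molecular weight (g/mol)
#' @return list of class `compound_params`
#' @export
compound_params <- function(solubility_cs_um = 50,
                            diffusion_cm2_s = 5e-6,
                            diffusion_layer_cm = 30e-4,
                            density_g_ml = 1.2,
                            initial_radius_um = 1.5,
                            permeability_tb_cm_s = 1e-6,
                            alveolar_permeability_multiplier = 10,
                            fu_plasma = 0.1, fu_tissue = 0.1,
                            kp_epithelium = 5, kp_subepithelium = 5,
                            k_in_per_h = 1, k_out_per_h = 0.5,
                            cl_ml_h = 6e4, vss_ml = 2e5, mw = 450) {
  p <- list(solubility_cs_um = solubility_cs_um,
            diffusion_cm2_s = diffusion_cm2_s,
            diffusion_layer_cm = diffusion_layer_cm,
            density_g_ml = density_g_ml,
            initial_radius_um = initial_radius_um,
            permeability_tb_cm_s = permeability_tb_cm_s,
            alveolar_permeability_multiplier = alveolar_permeability_multiplier,
            fu_plasma = fu_plasma, fu_tissue = fu_tissue,
            kp_epithelium = kp_epithelium,
            kp_subepithelium = kp_subepithelium,
            k_in_per_h = k_in_per_h, k_out_per_h = k_out_per_h,
            cl_ml_h = cl_ml_h, vss_ml = vss_ml, mw = mw)
  num <- unlist(p)
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("all compound parameters must be positive and finite")
  }
  stopifnot(fu_plasma <= 1, fu_tissue <= 1)
  class(p) <- "compound_params"
  p
}

#' Nernst-Brunner dissolution rate of monodisperse shrinking spheres
#'
#' `rate = (D/h) * A * (Cs - C)` with A the total surface area of
#' `n_particles` equal spheres at the current undissolved amount.
#' Supersaturation (C > Cs) would give a negative rate (precipitation);
#' it is clipped at zero, which the simulator flags.
#'
#' @param undissolved_nmol current undissolved amount (nmol)
#' @param n_particles number of particles (fixed at dosing)
#' @param solubility_cs_um,conc_um solubility and local ELF concentration
#' @param diffusion_cm2_s,diffusion_layer_cm Nernst-Brunner transport terms
#' @param density_g_ml,mw particle density and molecular weight
#' @param clip clip negative (precipitation) rates to zero (default TRUE)
#' @return dissolution rate in nmol/h
#' @export
nernst_brunner_rate <- function(undissolved_nmol, n_particles,
                                solubility_cs_um, conc_um,
                                diffusion_cm2_s, diffusion_layer_cm,
                                density_g_ml, mw, clip = TRUE) {
  if (undissolved_nmol <= 0 || n_particles <= 0) return(0)
  mass_g <- undissolved_nmol * 1e-9 * mw / n_particles
  r_cm <- (3 * mass_g / (4 * pi * density_g_ml))^(1 / 3)
  area <- n_particles * 4 * pi * r_cm^2
  rate <- 3600 * (diffusion_cm2_s / diffusion_layer_cm) * area *
    (solubility_cs_um - conc_um)
  if (clip) max(rate, 0) else rate
}

#' Assemble and validate a lung model specification
#'
#' Combines morphometry, compound parameters and systemic options into a
#' validated specification with per-generation permeabilities (alveolar =
#' multiplier x tracheobronchial) and regional blood flows. The
#' tracheobronchial region is perfused by the bronchial blood flow and the
#' alveolar region by the entire cardiac output, each distributed over
#' generations proportionally to tissue volume (constant flow per tissue
#' volume).
#'
#' @param morphometry a [default_airway_morphometry()]-shaped data.frame
#' @param compound a [compound_params()]
#' @param cardiac_output_ml_h total cardiac output
#' @param bronchial_flow_fraction fraction of cardiac output perfusing the
#'   tracheobronchial wall
#' @param epithelial_transfer_factor the epithelium <-> sub-epithelium
#'   exchange permeability as a multiple of the generation's ELF
#'   permeability
#' @return list of class `lung_model_spec`
#' @export
build_lung_model <- function(morphometry = default_airway_morphometry(),
                             compound = compound_params(),
                             cardiac_output_ml_h = 3e5,
                             bronchial_flow_fraction = 0.01,
                             epithelial_transfer_factor = 1) {
  m <- morphometry
  need <- c("generation", "region", "surface_area_cm2", "elf_volume_ml",
            "epithelium_volume_ml", "subepithelium_volume_ml",
            "mucociliary_rate_per_h")
  stopifnot(is.data.frame(m), all(need %in% names(m)), nrow(m) == 24,
            identical(as.integer(m$generation), 1:24))
  pos <- c("surface_area_cm2", "elf_volume_ml", "epithelium_volume_ml",
           "subepithelium_volume_ml")
  for (cn in pos) if (any(m[[cn]] <= 0)) stop("morphometry column ", cn, " must be positive")
  alv <- m$region == "alveolar"
  if (!identical(which(alv), 17:24)) {
    stop("generations 17-24 must be the alveolar region")
  }
  if (any(m$mucociliary_rate_per_h[alv] != 0)) {
    stop("mucociliary clearance must be zero in the alveolar region")
  }
  if (any(m$mucociliary_rate_per_h < 0)) stop("negative mucociliary rate")
  p_gen <- ifelse(alv,
                  compound$permeability_tb_cm_s * compound$alveolar_permeability_multiplier,
                  compound$permeability_tb_cm_s)
  tis_vol <- m$epithelium_volume_ml + m$subepithelium_volume_ml
  q_gen <- numeric(24)
  q_tb_total <- cardiac_output_ml_h * bronchial_flow_fraction
  q_gen[!alv] <- q_tb_total * tis_vol[!alv] / sum(tis_vol[!alv])
  q_gen[alv] <- cardiac_output_ml_h * tis_vol[alv] / sum(tis_vol[alv])
  structure(list(
    morphometry = m, compound = compound,
    permeability_cm_s = p_gen, blood_flow_ml_h = q_gen,
    cardiac_output_ml_h = cardiac_output_ml_h,
    bronchial_flow_fraction = bronchial_flow_fraction,
    epithelial_transfer_factor = epithelial_transfer_factor),
    class = "lung_model_spec")
}

#' Inhaled dose event
#'
#' @param total_dose_nmol total deposited + swallowed dose (nmol)
#' @param deposition_fraction_tb,deposition_fraction_alveolar fractions of
#'   the dose deposited in the tracheobronchial and alveolar regions
#'   (defaults 0.70 / 0.30); any remainder is swallowed immediately
#'   (extra-thoracic deposition)
#' @param formulation "solid_particles" (dissolving dry powder) or
#'   "solution"
#' @param deposition_weights optional length-24 non-negative vector giving
#'   the within-lung deposition pattern directly (overrides the regional
#'   fractions; normalised internally); the default splits each region's
#'   fraction over its generations proportionally to surface area
#' @return list of class `dose_event`
#' @export
dose_event <- function(total_dose_nmol,
                       deposition_fraction_tb = 0.70,
                       deposition_fraction_alveolar = 0.30,
                       formulation = c("solid_particles", "solution"),
                       deposition_weights = NULL) {
  formulation <- match.arg(formulation)
  stopifnot(total_dose_nmol > 0,
            deposition_fraction_tb >= 0, deposition_fraction_alveolar >= 0,
            deposition_fraction_tb + deposition_fraction_alveolar <= 1)
  if (!is.null(deposition_weights)) {
    stopifnot(length(deposition_weights) == 24, all(deposition_weights >= 0),
              sum(deposition_weights) > 0)
  }
  structure(list(total_dose_nmol = total_dose_nmol,
                 deposition_fraction_tb = deposition_fraction_tb,
                 deposition_fraction_alveolar = deposition_fraction_alveolar,
                 formulation = formulation,
                 deposition_weights = deposition_weights),
            class = "dose_event")
}

# per-generation deposited amounts (nmol) and the swallowed remainder
deposited_amounts <- function(model, dose) {
  m <- model$morphometry
  alv <- m$region == "alveolar"
  if (!is.null(dose$deposition_weights)) {
    w <- dose$deposition_weights / sum(dose$deposition_weights)
    lung_fraction <- dose$deposition_fraction_tb + dose$deposition_fraction_alveolar
    dep <- dose$total_dose_nmol * lung_fraction * w
  } else {
    dep <- numeric(24)
    sa <- m$surface_area_cm2
    dep[!alv] <- dose$total_dose_nmol * dose$deposition_fraction_tb *
      sa[!alv] / sum(sa[!alv])
    dep[alv] <- dose$total_dose_nmol * dose$deposition_fraction_alveolar *
      sa[alv] / sum(sa[alv])
  }
  list(lung = dep, swallowed = dose$total_dose_nmol - sum(dep))
}

#' Simulate lung and systemic disposition after an inhaled dose
#'
#' Stiff ODE integration (deSolve::lsoda, relative tolerance 1e-8) of the
#' generation-resolved flux model. Mass balance (lung + plasma + cleared +
#' swallowed vs dose) is asserted at every output time to a relative
#' residual of 1e-6; materially negative states abort with an error rather
#' than being clipped.
#'
#' @param model a [build_lung_model()] specification
#' @param dose a [dose_event()]
#' @param t_end_h simulation horizon (h)
#' @param dt_out_h output grid spacing (h)
#' @return object of class `lung_sim`: `time_h`; 24-column matrices
#'   `elf_conc_um`, `epithelium_conc_um`, `subepithelium_conc_um`,
#'   `solid_nmol`, `deep_epithelium_nmol`, `deep_subepithelium_nmol`;
#'   vectors `plasma_conc_um`, `cleared_nmol`, `swallowed_nmol`;
#'   `supersaturation_clipped` flag; the `model` and `dose` used
#' @export
simulate_lung <- function(model, dose, t_end_h = 24, dt_out_h = 0.1) {
  stopifnot(inherits(model, "lung_model_spec"), inherits(dose, "dose_event"))
  m <- model$morphometry
  cp <- model$compound
  dep <- deposited_amounts(model, dose)
  solid0 <- if (dose$formulation == "solid_particles") dep$lung else numeric(24)
  elf0 <- if (dose$formulation == "solution") dep$lung else numeric(24)
  # particle count per generation, fixed at dosing
  r0_cm <- cp$initial_radius_um * 1e-4
  m0_nmol <- (4 / 3) * pi * r0_cm^3 * cp$density_g_ml / cp$mw * 1e9
  n_part <- solid0 / m0_nmol
  v_elf <- m$elf_volume_ml
  v_epi <- m$epithelium_volume_ml
  v_sub <- m$subepithelium_volume_ml
  sa <- m$surface_area_cm2
  kmc <- m$mucociliary_rate_per_h
  pg <- model$permeability_cm_s * 3600            # cm/h
  pg_es <- pg * model$epithelial_transfer_factor  # epithelium <-> sub-epithelium
  q <- model$blood_flow_ml_h
  kpu_epi <- cp$kp_epithelium / cp$fu_plasma      # tissue : unbound partition
  kpu_sub <- cp$kp_subepithelium / cp$fu_plasma
  kin <- cp$k_in_per_h; kout <- cp$k_out_per_h
  dh <- 3600 * cp$diffusion_cm2_s / cp$diffusion_layer_cm  # cm/h
  supersat <- FALSE

  # state: s[1:24], e[25:48], epi[49:72], sub[73:96], de[97:120], ds[121:144],
  # plasma [145], cleared [146], swallowed [147]
  y0 <- c(solid0, elf0, numeric(24 * 4), 0, 0, dep$swallowed)
  rhs <- function(t, y, parms) {
    s <- y[1:24]; e <- y[25:48]; epi <- y[49:72]; sub <- y[73:96]
    de <- y[97:120]; ds <- y[121:144]
    apl <- y[145]
    c_elf <- e / v_elf
    cu_epi <- (epi / v_epi) / kpu_epi
    cu_sub <- (sub / v_sub) / kpu_sub
    c_pl <- apl / cp$vss_ml
    # dissolution (Nernst-Brunner, shrinking monodisperse spheres)
    j_dis <- numeric(24)
    act <- which(s > 0 & n_part > 0)
    if (length(act)) {
      mass_g <- s[act] * 1e-9 * cp$mw / n_part[act]
      r_cm <- (3 * mass_g / (4 * pi * cp$density_g_ml))^(1 / 3)
      area <- n_part[act] * 4 * pi * r_cm^2
      j <- dh * area * (cp$solubility_cs_um - c_elf[act])
      j_dis[act] <- pmax(j, 0)
    }
    # mucociliary transport g -> g-1 (solid + dissolved), trachea -> swallowed
    mc_s <- kmc * pmax(s, 0)
    mc_e <- kmc * pmax(e, 0)
    in_s <- c(mc_s[-1], 0)       # inflow from generation g+1
    in_e <- c(mc_e[-1], 0)
    # permeability fluxes
    j_perm <- pg * sa * (c_elf - cu_epi)
    j_es <- pg_es * sa * (cu_epi - cu_sub)
    j_blood <- q * (c_pl - cu_sub / cp$fu_plasma)  # into sub-epithelium
    d_s <- -j_dis - mc_s + in_s
    d_e <- j_dis - mc_e + in_e - j_perm
    d_epi <- j_perm - j_es - kin * epi + kout * de
    d_sub <- j_es + j_blood - kin * sub + kout * ds
    d_de <- kin * epi - kout * de
    d_ds <- kin * sub - kout * ds
    d_apl <- -sum(j_blood) - cp$cl_ml_h * c_pl
    d_cl <- cp$cl_ml_h * c_pl
    d_sw <- mc_s[1] + mc_e[1]
    list(c(d_s, d_e, d_epi, d_sub, d_de, d_ds, d_apl, d_cl, d_sw))
  }
  times <- seq(0, t_end_h, by = dt_out_h)
  sol <- deSolve::lsoda(y0, times, rhs, parms = NULL,
                        rtol = 1e-8, atol = 1e-12 * dose$total_dose_nmol + 1e-12)
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE integration failed; istate = ", attr(sol, "istate")[1])
  }
  y <- sol[, -1, drop = FALSE]
  neg_tol <- 1e-8 * dose$total_dose_nmol
  if (any(y < -neg_tol)) {
    stop("materially negative state encountered (min = ", min(y), " nmol)")
  }
  y[y < 0] <- 0  # sub-tolerance integrator noise only
  total <- rowSums(y)
  mb <- abs(total - dose$total_dose_nmol) / dose$total_dose_nmol
  if (any(mb > 1e-6)) {
    stop("mass-balance residual ", max(mb), " exceeds 1e-6")
  }
  # did dissolution ever get clipped for supersaturation?
  elf_cmax <- max(t(y[, 25:48]) / v_elf)
  supersat <- dose$formulation == "solid_particles" &&
    elf_cmax > cp$solubility_cs_um
  structure(list(
    time_h = times,
    solid_nmol = y[, 1:24, drop = FALSE],
    elf_conc_um = sweep(y[, 25:48, drop = FALSE], 2, v_elf, "/"),
    epithelium_conc_um = sweep(y[, 49:72, drop = FALSE], 2, v_epi, "/"),
    subepithelium_conc_um = sweep(y[, 73:96, drop = FALSE], 2, v_sub, "/"),
    deep_epithelium_nmol = y[, 97:120, drop = FALSE],
    deep_subepithelium_nmol = y[, 121:144, drop = FALSE],
    plasma_conc_um = y[, 145] / cp$vss_ml,
    cleared_nmol = y[, 146], swallowed_nmol = y[, 147],
    mass_balance_rel_error = max(mb),
    supersaturation_clipped = supersat,
    model = model, dose = dose), class = "lung_sim")
}

#' @export
print.lung_sim <- function(x, ...) {
  cat(sprintf("lung_sim: %.3g nmol %s, t = 0..%g h (%d points)\n",
              x$dose$total_dose_nmol, x$dose$formulation,
              max(x$time_h), length(x$time_h)))
  cat(sprintf("  peak ELF conc %.3g uM (generation %d); mass balance residual %.2g\n",
              max(x$elf_conc_um),
              which.max(apply(x$elf_conc_um, 2, max)),
              x$mass_balance_rel_error))
  if (x$supersaturation_clipped) {
    cat("  note: ELF exceeded solubility; precipitation not modelled (rate clipped at 0)\n")
  }
  invisible(x)
}

#' @export
plot.lung_sim <- function(x, generations = c(1, 4, 8, 12, 16, 20, 24), ...) {
  cols <- grDevices::hcl.colors(length(generations), "viridis")
  ymax <- max(x$elf_conc_um[, generations])
  graphics::plot(NULL, xlim = range(x$time_h), ylim = c(0, ymax),
                 xlab = "time (h)", ylab = "ELF concentration (uM)",
                 main = "ELF exposure by airway generation", ...)
  for (i in seq_along(generations)) {
    graphics::lines(x$time_h, x$elf_conc_um[, generations[i]], col = cols[i])
  }
  graphics::legend("topright", legend = paste("gen", generations),
                   col = cols, lty = 1, cex = 0.8)
  invisible(x)
}

#' Regional ELF exposure summary
#'
#' The regional ELF concentration at each time is the ELF-volume-weighted
#' mean over member generations; Cmax is its maximum over time.
#'
#' @param result a [simulate_lung()] result
#' @param regions named list of generation index vectors
#' @return data.frame with `region`, `cmax_um`, `tmax_h`
#' @export
elf_region_summary <- function(result,
                               regions = list(upper_tb = 1:6,
                                              lower_tb = 7:16,
                                              alveolar = 17:24)) {
  stopifnot(inherits(result, "lung_sim"), length(regions) >= 1)
  v_elf <- result$model$morphometry$elf_volume_ml
  rows <- lapply(names(regions), function(rn) {
    gs <- regions[[rn]]
    if (!length(gs)) stop("empty region: ", rn)
    w <- v_elf[gs] / sum(v_elf[gs])
    prof <- as.vector(result$elf_conc_um[, gs, drop = FALSE] %*% w)
    data.frame(region = rn, cmax_um = max(prof),
               tmax_h = result$time_h[which.max(prof)],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Map regional ELF exposure onto the in vitro dose-response curve
#'
#' For each lung region, relates the modelled unbound ELF Cmax to the
#' assay IC50: exposure ratio Cmax/IC50, the predicted normalized response
#' at Cmax, and an at-risk flag when Cmax reaches `at_risk_fraction` of the
#' IC50 (default 0.5). If the fit has no established IC50 all regions are
#' flagged `no_in_vitro_effect_detected`.
#'
#' @param region_summary result of [elf_region_summary()], or a named
#'   numeric vector of regional Cmax values (uM)
#' @param fit an [fit_ic50()] result
#' @param at_risk_fraction fraction of the IC50 above which a region is
#'   flagged at risk
#' @return data.frame: region, cmax_um, ic50_um, exposure_ratio,
#'   predicted_response, at_risk, note
#' @export
map_exposure_to_ic50 <- function(region_summary, fit, at_risk_fraction = 0.5) {
  stopifnot(inherits(fit, "ic50_fit"))
  if (is.numeric(region_summary)) {
    region_summary <- data.frame(region = names(region_summary),
                                 cmax_um = unname(region_summary))
  }
  cmax <- region_summary$cmax_um
  if (!fit$established) {
    return(data.frame(region = region_summary$region, cmax_um = cmax,
                      ic50_um = NA_real_, exposure_ratio = NA_real_,
                      predicted_response = NA_real_, at_risk = FALSE,
                      note = "no_in_vitro_effect_detected",
                      stringsAsFactors = FALSE))
  }
  data.frame(region = region_summary$region, cmax_um = cmax,
             ic50_um = fit$ic50_um, exposure_ratio = cmax / fit$ic50_um,
             predicted_response = predict(fit, pmax(cmax, .Machine$double.eps)),
             at_risk = cmax >= at_risk_fraction * fit$ic50_um,
             note = "", stringsAsFactors = FALSE)
}
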