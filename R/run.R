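# Pipeline driver: low-level SCF -> localize/select -> AO + auxiliary
# reduction -> embedded high-level SCF -> energy assembly, plus the
# threshold-sweep utility and plain-text / key-value reporting.

#' Run configuration
#'
#' Collects every tunable of the embedding pipeline with the recommended
#' defaults: `eps_ao = 1e-4`, and for the auxiliary schemes
#' `eps_naf = 5e-4` Eh, `eps_dom = 2.0` Eh, `eps_mull = 0.3`.  Exactly one
#' auxiliary scheme is active (`"none"`, `"naf"`, `"mulliken"`, `"ldf"`).
#'
#' @param ... overrides of the defaults listed below
#' @return a named list of class `less_config`
#' @export
less_config <- function(...) {
  cfg <- list(
    geometry = NULL, charge = 0L, point_charges = NULL,
    active_atoms = integer(),
    ll_functional = "pbe", hl_functional = "pbe0",
    ao_basis = "dz", aux_basis = "autoaux",
    eps_ao = 1e-4, ao_scheme = "mulliken",
    aux_scheme = "none", eps_naf = 5e-4, eps_dom = 2.0, eps_mull = 0.3,
    lowdin_cut = 0.05,
    mode = "incore", memory_budget = 4e9, screen_threshold = 1e-10,
    embed_mode = "huzinaga", alpha = 1e6,
    tau_sel = 0.4, tau_drop = 1e-3,
    grid_level = 2L, scf = list(),
    checkpoint = NULL, report = NULL, verbose = FALSE
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(cfg, over)
  if (!cfg$aux_scheme %in% c("none", "naf", "mulliken", "ldf")) {
    stop("aux_scheme must be one of none/naf/mulliken/ldf")
  }
  for (f in c("eps_ao", "eps_naf", "eps_dom", "eps_mull")) {
    if (!is.null(cfg[[f]]) && cfg[[f]] < 0) stop(f, " must be >= 0")
  }
  class(cfg) <- "less_config"
  cfg
}

#' Load a configuration file
#'
#' Flat YAML document with the [less_config()] field names; explicit
#' arguments in `...` override file values (precedence CLI > file >
#' defaults).
#'
#' @param path YAML file path
#' @param ... overrides
#' @export
read_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  do.call(less_config, utils::modifyList(vals, list(...)))
}

active_atom_parse <- function(x, n_atoms) {
  if (is.numeric(x)) return(sort(unique(as.integer(x))))
  toks <- unlist(strsplit(as.character(x), ","))
  out <- integer()
  for (t in toks) {
    t <- trimws(t)
    if (grepl("-", t)) {
      rng <- as.integer(strsplit(t, "-")[[1]])
      out <- c(out, seq(rng[1], rng[2]))
    } else {
      out <- c(out, as.integer(t))
    }
  }
  out <- sort(unique(out))
  if (any(out < 1 | out > n_atoms)) stop("active atom index out of range")
  out
}

#' Run the full embedding pipeline on one system
#'
#' The sequence is: full-system low-level SCF (complete AO basis), orbital
#' localization and active-orbital selection, AO truncation (unless
#' `eps_ao` is `NULL`), auxiliary-basis reduction with the configured
#' scheme, embedded high-level SCF, and assembly of the total energy.
#'
#' @param system a `less_system` (alternatively set `config$geometry` to an
#'   XYZ path)
#' @param active_atoms active atom indices (overrides `config$active_atoms`)
#' @param config a [less_config()]
#' @return object of class `less_run`: the `less_energy`, both SCF states,
#'   the partition, reduction bookkeeping and per-stage wall times
#' @export
run_embedding <- function(system = NULL, active_atoms = NULL,
                          config = less_config()) {
  t_all <- proc.time()[3]
  timings <- c()
  tick <- function(name, t0) {
    timings[[name]] <<- round(proc.time()[3] - t0, 3)
  }
  if (is.null(system)) {
    if (is.null(config$geometry)) stop("no system and no geometry path")
    pc <- if (!is.null(config$point_charges)) {
      read_point_charges(config$point_charges)
    } else NULL
    system <- read_xyz(config$geometry, charge = config$charge,
                       ao_basis = config$ao_basis,
                       aux_basis = config$aux_basis)
    system$point_charges <- pc
  }
  if (is.null(active_atoms)) active_atoms <- config$active_atoms
  active_atoms <- active_atom_parse(active_atoms, length(system$symbols))

  t0 <- proc.time()[3]
  handle <- backend_handle(system, grid_level = config$grid_level)
  T_ll <- build_tensors(handle, mode = config$mode,
                        screen_threshold = config$screen_threshold,
                        memory_budget = config$memory_budget)
  oe <- one_electron(handle)
  n_occ <- system$n_electrons / 2L
  low <- scf_solve(handle, T_ll, config$ll_functional, oe$h, n_occ,
                   options = config$scf)
  tick("low_scf", t0)
  if (!low$converged) stop("low-level SCF did not converge")

  t0 <- proc.time()[3]
  part <- localize_and_select(low, handle, active_atoms,
                              tau_sel = config$tau_sel)
  tick("localize", t0)

  t0 <- proc.time()[3]
  if (!is.null(config$eps_ao)) {
    plan <- ao_reduction_plan(handle, part, eps_ao = config$eps_ao,
                              tau_drop = config$tau_drop)
    part$C_A_red <- plan$C_A_red
    part$C_B_red <- plan$C_B_red
    kept_ao <- plan$kept_ao
  } else {
    plan <- NULL
    kept_ao <- seq_len(handle$ao$nbf)
  }
  aux_info <- list(scheme = config$aux_scheme,
                   retention = 100, kept_aux = NULL, naf = NULL)
  if (config$aux_scheme != "none") {
    T_red <- build_tensors(handle, kept_ao = kept_ao, mode = config$mode,
                           screen_threshold = config$screen_threshold,
                           memory_budget = config$memory_budget)
    if (config$aux_scheme == "naf") {
      naf <- naf_build(part$C_A, T_red, config$eps_naf)
      aux_info$naf <- naf
      aux_info$retention <- aux_retention(handle, naf)
    } else if (config$aux_scheme == "mulliken") {
      naf <- naf_build(part$C_A, T_red, config$eps_naf)
      kept_aux <- generalized_mulliken(naf, aux_overlap(handle),
                                       config$eps_mull,
                                       shell_map(handle, "aux"))
      aux_info$kept_aux <- kept_aux
      aux_info$retention <- aux_retention(handle, kept_aux)
    } else {
      kept_aux <- ldf_domains(part$C_A, handle, config$eps_dom,
                              lowdin_cut = config$lowdin_cut)
      aux_info$kept_aux <- kept_aux
      aux_info$retention <- aux_retention(handle, kept_aux)
    }
  }
  T_hl <- build_tensors(handle, kept_ao = kept_ao,
                        kept_aux = aux_info$kept_aux, naf = aux_info$naf,
                        mode = config$mode,
                        screen_threshold = config$screen_threshold,
                        memory_budget = config$memory_budget)
  tick("reduction", t0)

  t0 <- proc.time()[3]
  h_emb <- embedding_potential(handle, config$ll_functional,
                               D_AB = low$D, D_A = part$D_A, T = T_ll,
                               C_AB = low$C_occ, C_A = part$C_A)
  high <- embedded_scf(handle, T_hl, part, config$hl_functional, h_emb,
                       mode = config$embed_mode, alpha = config$alpha,
                       options = config$scf)
  tick("high_scf", t0)
  if (!high$converged) stop("embedded high-level SCF did not converge")

  energy <- assemble_energy(low, part, high, h_emb, handle, T_ll,
                            config$ll_functional)
  timings[["total"]] <- round(proc.time()[3] - t_all, 3)
  run <- list(energy = energy, low = low, high = high, partition = part,
              plan = plan, aux_info = aux_info, config = config,
              handle = handle,
              ao_retention = if (is.null(plan)) 100 else 100 * plan$retention,
              aux_retention = aux_info$retention,
              dropped_env = if (is.null(plan)) 0L else plan$dropped_env_count,
              timings = timings)
  class(run) <- "less_run"
  if (!is.null(config$checkpoint)) {
    write_checkpoint(low, T_ll, config$checkpoint)
  }
  if (!is.null(config$report)) {
    writeLines(format_report(run), config$report)
  }
  run
}

#' @export
print.less_run <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' Machine-readable report block
#'
#' Key-value lines echoing the energy decomposition (Hartree), MO counts,
#' retention percentages, iteration counts and stage wall times.
#'
#' @param run a `less_run`
#' @return character vector of `key = value` lines
#' @export
format_report <- function(run) {
  e <- run$energy
  kv <- c(
    sprintf("E_LL_full   = %.10f", e$E_LL_full),
    sprintf("E_LL_act    = %.10f", e$E_LL_act),
    sprintf("E_HL_act    = %.10f", e$E_HL_act),
    sprintf("E_corr      = %.10f", e$E_corr),
    sprintf("E_total     = %.10f", e$E_total),
    sprintf("n_active_mo = %d", e$n_act),
    sprintf("n_env_mo    = %d", e$n_env),
    sprintf("ao_retention_pct  = %.2f", run$ao_retention),
    sprintf("aux_retention_pct = %.2f", run$aux_retention),
    sprintf("dropped_env_mos   = %d", run$dropped_env),
    sprintf("low_scf_iters  = %d", run$low$n_iter),
    sprintf("high_scf_iters = %d", run$high$n_iter),
    sprintf("aux_scheme = %s", run$aux_info$scheme),
    sprintf("mode = %s", run$config$mode)
  )
  tv <- vapply(names(run$timings), function(n) {
    sprintf("t_%s_s = %.3f", n, run$timings[[n]])
  }, "")
  c("# lessemb embedding report (energies in Hartree)", kv, tv)
}

#' Reaction energy of a fixture under one configuration
#'
#' Runs [run_embedding()] for every species of a reaction fixture (a list
#' of `(system, coeff, active_atoms)` entries) and returns the
#' stoichiometric energy sum.
#'
#' @param reaction fixture reaction, e.g. from [build_sn2_pair()]
#' @param config a [less_config()]
#' @return list with `dE` (Hartree), `runs`, `mean_aux_retention`
#' @export
reaction_energy <- function(reaction, config = less_config()) {
  runs <- lapply(reaction$species, function(sp) {
    run_embedding(sp$system, sp$active_atoms, config)
  })
  dE <- sum(vapply(seq_along(runs), function(i) {
    reaction$species[[i]]$coeff * runs[[i]]$energy$E_total
  }, numeric(1)))
  list(dE = dE, runs = runs,
       mean_aux_retention = mean(vapply(runs, `[[`, 0, "aux_retention")))
}

#' Threshold sweep of an auxiliary reduction scheme
#'
#' For a reaction fixture, computes one reduction-free reference (AO
#' reduction only) per species, then the reaction-energy error of the
#' chosen auxiliary scheme over a threshold grid, reported in kcal/mol
#' together with the mean retained fraction of the fitting basis.
#'
#' @param reaction fixture reaction (>= 2 species)
#' @param scheme `"naf"`, `"mulliken"` or `"ldf"`
#' @param thresholds numeric vector of scheme thresholds
#' @param config base configuration (its `aux_scheme` is ignored)
#' @return data.frame with columns `threshold`, `retention_pct`,
#'   `error_kcal`; the reference reaction energy (Hartree) is attached as
#'   attribute `"dE_ref"`
#' @export
run_sweep <- function(reaction, scheme = c("ldf", "naf", "mulliken"),
                      thresholds, config = less_config()) {
  scheme <- match.arg(scheme)
  if (length(reaction$species) < 2) {
    stop("a sweep needs a reaction with at least two species")
  }
  config$aux_scheme <- "none"
  ref <- reaction_energy(reaction, config)
  rows <- lapply(thresholds, function(th) {
    cfg <- config
    cfg$aux_scheme <- scheme
    if (scheme == "naf") cfg$eps_naf <- th
    if (scheme == "mulliken") cfg$eps_mull <- th
    if (scheme == "ldf") cfg$eps_dom <- th
    r <- if (th == 0 && scheme != "naf") ref else reaction_energy(reaction, cfg)
    data.frame(threshold = th, retention_pct = r$mean_aux_retention,
               error_kcal = (r$dE - ref$dE) * kcal_per_hartree)
  })
  out <- do.call(rbind, rows)
  attr(out, "dE_ref") <- ref$dE
  out
}
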