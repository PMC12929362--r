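# Emission of the MD protocol as GROMACS-style parameter (.mdp) files and
# a human-readable run plan.  Only configuration is generated here; no MD
# engine is invoked.

#' Molecular-dynamics protocol specification
#'
#' Captures the simulation protocol for the aptamer systems: solvated
#' triclinic box neutralized with Na+/Cl-, steepest-descent minimization,
#' 100 ps NVT and 100 ps NPT equilibration, then a 200 ns NPT production
#' run, at 300 K and 310 K, with 1.2 nm short-range cutoffs, PME
#' long-range electrostatics, velocity-rescale (modified Berendsen)
#' thermostat and Parrinello-Rahman barostat at 1 atm, CHARMM27 force
#' field with TIP3P water.
#'
#' @param temperatures simulation temperatures in K (default
#'   `c(300, 310)`).
#' @param production_ns production run length, ns (default 200).
#' @param equil_ps length of each equilibration stage (NVT, NPT), ps
#'   (default 100).
#' @param cutoff_nm short-range electrostatic and van der Waals cutoff,
#'   nm (default 1.2).
#' @param timestep_fs integration timestep, fs (default 2; assumed, with
#'   constrained hydrogens).
#' @param pressure_atm reference pressure, atm (default 1).
#' @param tau_t,tau_p thermostat/barostat coupling constants, ps
#'   (defaults 0.1 and 2.0; assumed).
#' @param forcefield,water force-field and water-model tags (defaults
#'   `"charmm27"`, `"tip3p"`).
#' @return an object of class `protocol_spec`.
#' @export
protocol_spec <- function(temperatures = c(300, 310), production_ns = 200,
                          equil_ps = 100, cutoff_nm = 1.2, timestep_fs = 2,
                          pressure_atm = 1, tau_t = 0.1, tau_p = 2.0,
                          forcefield = "charmm27", water = "tip3p") {
  stopifnot(all(temperatures > 0), production_ns > 0, equil_ps > 0,
            cutoff_nm > 0, timestep_fs > 0, pressure_atm > 0)
  structure(list(temperatures = temperatures,
                 production_ns = production_ns, equil_ps = equil_ps,
                 cutoff_nm = cutoff_nm, timestep_fs = timestep_fs,
                 pressure_atm = pressure_atm, tau_t = tau_t, tau_p = tau_p,
                 forcefield = forcefield, water = water,
                 box = "triclinic", ions = "Na+/Cl- to neutrality",
                 minimization = "steepest descent"),
            class = "protocol_spec")
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat("protocol_spec:", x$production_ns, "ns production at",
      paste(x$temperatures, collapse = "/"), "K;",
      x$equil_ps, "ps NVT + NPT equilibration;",
      x$cutoff_nm, "nm cutoffs; PME; v-rescale; Parrinello-Rahman;",
      x$forcefield, "+", x$water, "\n")
  invisible(x)
}

.mdp_stages <- c("minim", "nvt", "npt", "production")

#' Emit a GROMACS-style .mdp parameter file
#'
#' Generates the key=value parameter text for one protocol stage.  Step
#' counts always satisfy steps x timestep = requested duration exactly
#' (e.g. 200 ns at 2 fs -> 100,000,000 steps; 100 ps -> 50,000 steps).
#' Pressure is expressed in bar (1 atm = 1.01325 bar).  Values the
#' protocol leaves unstated (timestep, coupling constants) are flagged as
#' assumptions in the file header.
#'
#' @param spec a [protocol_spec].
#' @param stage one of `"minim"`, `"nvt"`, `"npt"`, `"production"`.
#' @param temperature temperature (K) for this file; defaults to the
#'   first entry of `spec$temperatures`.
#' @return the parameter text as a single character string (byte-stable
#'   for identical inputs).
#' @examples
#' cat(emit_mdp(protocol_spec(), "production", temperature = 310))
#' @export
emit_mdp <- function(spec, stage = c("minim", "nvt", "npt", "production"),
                     temperature = spec$temperatures[1]) {
  stopifnot(inherits(spec, "protocol_spec"))
  stage <- match.arg(stage)
  dt_ps <- spec$timestep_fs / 1000
  nsteps <- switch(stage,
    minim = 50000L,
    nvt = ,
    npt = as.integer(round(spec$equil_ps / dt_ps)),
    production = round(spec$production_ns * 1000 / dt_ps))
  hdr <- c(
    sprintf("; %s stage parameters", stage),
    "; timestep and coupling constants are assumed values (not part of the",
    ";   published protocol); all other settings follow it",
    "")
  common <- c(
    sprintf("cutoff-scheme            = Verlet"),
    sprintf("rcoulomb                 = %.1f", spec$cutoff_nm),
    sprintf("rvdw                     = %.1f", spec$cutoff_nm),
    sprintf("coulombtype              = PME"))
  if (stage == "minim") {
    body <- c(
      "integrator               = steep",
      "emtol                    = 1000.0",
      "emstep                   = 0.01",
      sprintf("nsteps                   = %.0f", nsteps),
      common,
      "; no temperature or pressure coupling during minimization",
      "tcoupl                   = no",
      "pcoupl                   = no")
  } else {
    body <- c(
      "integrator               = md",
      sprintf("dt                       = %.3f", dt_ps),
      sprintf("nsteps                   = %.0f", nsteps),
      common,
      "constraints              = h-bonds",
      "tcoupl                   = v-rescale   ; modified Berendsen thermostat",
      sprintf("tc-grps                  = System"),
      sprintf("tau_t                    = %.1f", spec$tau_t),
      sprintf("ref_t                    = %d", as.integer(temperature)))
    if (stage == "nvt") {
      body <- c(body, "pcoupl                   = no",
                "gen_vel                  = yes",
                sprintf("gen_temp                 = %d", as.integer(temperature)))
    } else {
      body <- c(body,
        "pcoupl                   = Parrinello-Rahman",
        "pcoupltype               = isotropic",
        sprintf("tau_p                    = %.1f", spec$tau_p),
        sprintf("ref_p                    = %.5f  ; %g atm in bar",
                spec$pressure_atm * 1.01325, spec$pressure_atm),
        "compressibility          = 4.5e-5",
        "gen_vel                  = no")
    }
  }
  paste(c(hdr, body, ""), collapse = "\n")
}

#' Emit a human-readable run plan
#'
#' Orders the full workflow for one molecule: solvation in a triclinic
#' box, neutralization with Na+/Cl- counterions, steepest-descent
#' minimization, NVT and NPT equilibration, production at each
#' temperature (duplicate runs with temperature as the sole variable),
#' and the post-run RMSD and hydrogen-bond analyses, naming the .mdp
#' files [emit_mdp] produces.
#'
#' @param spec a [protocol_spec].
#' @param molecule molecule label (e.g. `"LN-A6"`).
#' @return the plan as a single character string.
#' @export
emit_run_plan <- function(spec, molecule = "molecule") {
  stopifnot(inherits(spec, "protocol_spec"))
  temps <- spec$temperatures
  steps <- c(
    sprintf("# MD run plan: %s", molecule),
    "",
    sprintf("Force field: %s with %s explicit water.", spec$forcefield,
            spec$water),
    sprintf("System is simulated %s, with temperature as the sole experimental variable (%s K).",
            if (length(temps) > 1) sprintf("in %s (%d runs)",
              if (length(temps) == 2) "duplicate" else "replicate",
              length(temps)) else "once",
            paste(temps, collapse = ", ")),
    "",
    sprintf("1. Solvate the %s model in a %s box (%s water).", molecule,
            spec$box, spec$water),
    sprintf("2. Add counterions (%s).", spec$ions),
    sprintf("3. Energy minimization: %s (minim.mdp).", spec$minimization),
    sprintf("4. NVT equilibration, %g ps (nvt.mdp).", spec$equil_ps),
    sprintf("5. NPT equilibration, %g ps (npt.mdp).", spec$equil_ps),
    sprintf("6. NPT production, %g ns at each temperature (%s).",
            spec$production_ns,
            paste(sprintf("production_%dK.mdp", as.integer(temps)),
                  collapse = ", ")),
    "7. Post-run analysis: superposition RMSD vs the reference structure",
    "   and intramolecular hydrogen-bond count per frame; report per-run",
    "   mean and SD.",
    "")
  paste(steps, collapse = "\n")
}
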