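# Simulator for SRB viability plates: four-parameter logistic response
# curves for a sensitive parental line and resistant clones with planted
# fold-resistance, read out as raw 490 nm absorbances with background and
# untreated wells.

#' Four-parameter logistic response
#'
#' `bottom + (top - bottom) / (1 + 10^(hill * (log10(conc) - log10(ic50))))`;
#' positive `hill` gives a response decreasing with concentration.
#'
#' @param conc Concentrations (nM), strictly positive.
#' @param bottom,top Lower/upper response asymptotes.
#' @param ic50 Inflection concentration (nM).
#' @param hill Hill slope.
#' @return Response values.
#' @export
fourpl_response <- function(conc, bottom, top, ic50, hill) {
  bottom + (top - bottom) / (1 + 10^(hill * (log10(conc) - log10(ic50))))
}

#' Parameters for the viability-plate simulator
#'
#' Defaults emulate the study's assay: parental IC50 62.4 nM, resistant
#' clones 38- to 62-fold resistant, duplicate wells per concentration.
#'
#' @param ic50_wt Parental IC50 (nM).
#' @param fold_resistance_range Uniform range of planted clone/parental IC50
#'   ratios.
#' @param hill Hill slope of the generating curves.
#' @param bottom,top Response asymptotes of the generating curves.
#' @param cv Multiplicative (log-normal) well noise; 0 gives exact curves.
#' @param concentrations Dose grid (nM), strictly positive and increasing.
#' @param replicates Wells per concentration within one experiment
#'   (duplicates by default).
#' @param n_experiments Independent experiments pooled into one plate table
#'   (default 3, each contributing `replicates` wells per concentration plus
#'   its own untreated and background wells).
#' @param n_clones Resistant clones simulated alongside the parental line.
#' @param bg_abs Background absorbance (no-cell wells).
#' @param span_abs Absorbance span between background and untreated wells.
#' @param seed Integer seed.
#' @return A `viability_sim_params` list.
#' @export
viability_sim_params <- function(ic50_wt = 62.4,
                                 fold_resistance_range = c(38, 62),
                                 hill = 1,
                                 bottom = 0,
                                 top = 1,
                                 cv = 0.05,
                                 concentrations = 10^seq(0, 5.5, by = 0.5),
                                 replicates = 2L,
                                 n_experiments = 3L,
                                 n_clones = 10L,
                                 bg_abs = 0.08,
                                 span_abs = 1.5,
                                 seed = 1L) {
  stopifnot(fold_resistance_range[1] <= fold_resistance_range[2],
            all(concentrations > 0), !is.unsorted(concentrations, strictly = TRUE),
            replicates >= 1L, n_experiments >= 1L, ic50_wt > 0)
  structure(list(ic50_wt = ic50_wt,
                 fold_resistance_range = fold_resistance_range,
                 hill = hill, bottom = bottom, top = top, cv = cv,
                 concentrations = concentrations, replicates = replicates,
                 n_experiments = n_experiments, n_clones = n_clones,
                 bg_abs = bg_abs, span_abs = span_abs, seed = seed),
            class = "viability_sim_params")
}

.sim_plate <- function(line, ic50, p) {
  conc <- rep(p$concentrations, each = p$replicates * p$n_experiments)
  n_untr <- 4L * p$n_experiments
  n_bg <- 2L * p$n_experiments
  resp <- fourpl_response(conc, p$bottom, p$top, ic50, p$hill)
  noise <- if (p$cv > 0) exp(rnorm(length(conc), 0, p$cv)) else rep(1, length(conc))
  untr_noise <- if (p$cv > 0) exp(rnorm(n_untr, 0, p$cv)) else rep(1, n_untr)
  tibble::tibble(
    well = c(sprintf("T%03d", seq_along(conc)),
             sprintf("U%02d", seq_len(n_untr)),
             sprintf("B%02d", seq_len(n_bg))),
    concentration_nM = c(conc, rep(0, n_untr + n_bg)),
    absorbance_490 = c(p$bg_abs + p$span_abs * resp * noise,
                       p$bg_abs + p$span_abs * p$top * untr_noise,
                       rep(p$bg_abs, n_bg)),
    role = c(rep("treated", length(conc)), rep("untreated", n_untr),
             rep("background", n_bg))
  )
}

#' Simulate SRB viability plates
#'
#' One plate for the parental line and one per resistant clone; clone IC50s
#' are `ic50_wt` times a uniform draw from `fold_resistance_range`.
#'
#' @param p A [viability_sim_params()] object.
#' @return A `viability_sim` list: `plates` (named list of plate tibbles with
#'   columns `well`, `concentration_nM`, `absorbance_490`, `role`), `truth`
#'   (tibble `line`, `ic50`, `fold`, plus curve parameters), `params`.
#' @export
simulate_viability <- function(p) {
  stopifnot(inherits(p, "viability_sim_params"))
  withr::with_seed(p$seed, {
    folds <- runif(p$n_clones, p$fold_resistance_range[1],
                   p$fold_resistance_range[2])
    lines <- c("parental", sprintf("clone%02d", seq_len(p$n_clones)))
    ic50s <- c(p$ic50_wt, p$ic50_wt * folds)
    plates <- purrr::map2(lines, ic50s, function(ln, ic) .sim_plate(ln, ic, p))
    names(plates) <- lines
    structure(list(
      plates = plates,
      truth = tibble::tibble(
        line = lines, ic50 = ic50s, fold = c(1, folds),
        bottom = p$bottom, top = p$top, hill = p$hill
      ),
      params = p
    ), class = "viability_sim")
  })
}

#' Write a viability simulation to files
#'
#' @param sim A `viability_sim`.
#' @param dir Output directory; one `plate_<line>.csv` per line plus
#'   `truth.json`.
#' @return Invisibly, the written paths.
#' @export
write_viability_files <- function(sim, dir) {
  stopifnot(inherits(sim, "viability_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::imap_chr(sim$plates, function(plate, line) {
    path <- file.path(dir, paste0("plate_", line, ".csv"))
    write.csv(plate, path, row.names = FALSE)
    path
  })
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, truth_path))
}

#' Write a deterministic fixture set
#'
#' Presets bundle the simulators at the study-like settings used throughout
#' the test suite: `dacr_like` (4 clones, ~9 passenger genes each, 1
#' silenced), `aacr_like` (7 clones, ~6 passengers, causal gene mutated in
#' 5, silenced in 1, absent in 1), `pulldown_default`, `viability_default`.
#'
#' @param out_dir Output directory.
#' @param preset One of `"dacr_like"`, `"aacr_like"`, `"pulldown_default"`,
#'   `"viability_default"`.
#' @return Invisibly, the written paths.
#' @export
write_fixtures <- function(out_dir, preset) {
  switch(
    preset,
    dacr_like = write_screen_files(
      simulate_resistance_screen(screen_sim_params(
        n_clones = 4L, passenger_mean = 9, silenced_clone_count = 1L,
        seed = 20201L)),
      out_dir),
    aacr_like = write_screen_files(
      simulate_resistance_screen(screen_sim_params(
        n_clones = 7L, passenger_mean = 6, silenced_clone_count = 1L,
        unexplained_clone_count = 1L, seed = 20202L)),
      out_dir),
    pulldown_default = write_pulldown_files(
      simulate_pulldown(pulldown_sim_params(seed = 20203L)), out_dir),
    viability_default = write_viability_files(
      simulate_viability(viability_sim_params(seed = 20204L)), out_dir),
    stop("unknown preset ", sQuote(preset), call. = FALSE)
  )
}
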