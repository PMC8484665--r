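#' Simulation configuration
#'
#' Defaults are the desk-scale study conditions: 29 diploids in five regions
#' (6/6/6/6/5), human-like rates (mutation 1.25e-8, recombination 1e-8 per
#' bp per generation), 29 years per generation, one 5 Mb chromosome.
#'
#' @param generation_time years per generation
#' @param mutation_rate per bp per generation
#' @param recombination_rate per bp per generation
#' @param sequence_length bp
#' @param samples_per_region named integer vector over regions G,R,U,P,B
#' @param seed integer seed for the simulator
#' @return list of class `pp_config`
#' @export
model_config <- function(generation_time = 29, mutation_rate = 1.25e-8,
                         recombination_rate = 1e-8, sequence_length = 5e6,
                         samples_per_region = c(G = 6, R = 6, U = 6, P = 6, B = 5),
                         seed = 1L) {
  if (generation_time <= 0)
    stop_pp("generation_time must be > 0", "pyrenpop_validation_error")
  if (!setequal(names(samples_per_region), the_regions))
    stop_pp("samples_per_region must name exactly G,R,U,P,B",
            "pyrenpop_validation_error")
  structure(list(generation_time = generation_time,
                 mutation_rate = mutation_rate,
                 recombination_rate = recombination_rate,
                 sequence_length = sequence_length,
                 samples_per_region = samples_per_region[the_regions],
                 seed = as.integer(seed)),
            class = "pp_config")
}

python_bin <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) stop_pp("no python interpreter on PATH", "pyrenpop_config_error")
  p
}

coalsim_script <- function() {
  s <- system.file("python", "coalsim.py", package = "pyrenpop")
  if (!nzchar(s)) stop_pp("coalsim.py not found in installed package",
                          "pyrenpop_config_error")
  s
}

run_coalsim <- function(jobs) {
  jf <- tempfile(fileext = ".json")
  of <- tempfile(fileext = ".txt")
  on.exit(unlink(c(jf, of)), add = TRUE)
  jsonlite::write_json(list(jobs = jobs), jf, auto_unbox = TRUE, digits = NA)
  st <- system2(python_bin(), c(coalsim_script(), jf, of),
                stdout = TRUE, stderr = TRUE)
  code <- attr(st, "status") %||% 0L
  if (code != 0L)
    stop_pp(paste("coalescent simulator failed:\n",
                  paste(st, collapse = "\n")), "pyrenpop_sim_error")
  parse_coalsim_output(of)
}

parse_coalsim_output <- function(path) {
  lines <- readLines(path)
  heads <- grep("^#JOB", lines)
  out <- vector("list", length(heads))
  for (b in seq_along(heads)) {
    hd <- strsplit(lines[heads[b]], " ", fixed = TRUE)[[1]]
    nsites <- as.integer(hd[3]); nhap <- as.integer(hd[4])
    if (nsites == 0L) {
      out[[b]] <- list(haplotypes = matrix(0L, 0, 0), positions = numeric(0))
      next
    }
    pos <- as.numeric(strsplit(substring(lines[heads[b] + 1L], 3L), " ",
                               fixed = TRUE)[[1]])
    hl <- lines[(heads[b] + 2L):(heads[b] + 1L + nhap)]
    h <- matrix(0L, nhap, nsites)
    for (i in seq_len(nhap)) h[i, ] <- as.integer(charToRaw(hl[i])) - 48L
    out[[b]] <- list(haplotypes = h, positions = pos)
  }
  out
}

params_to_job <- function(params, config, id, ancestry_seed, mutation_seed) {
  p <- validate_params(params)
  gt <- config$generation_time
  g_GRUBP <- max(1, round(p$t_GRUBP / gt))
  g_GR <- min(max(1, round(p$t_GR / gt)), g_GRUBP)
  g_UPB <- min(max(1, round(p$t_UPB / gt)), g_GRUBP)
  list(id = id, mode = "five_pop",
       params = list(Ne_G = p$Ne_G, Ne_R = p$Ne_R, Ne_U = p$Ne_U,
                     Ne_P = p$Ne_P, Ne_B = p$Ne_B, Ne_GR = p$Ne_GR,
                     Ne_UPB = p$Ne_UPB, Ne_GRUBP = p$Ne_GRUBP,
                     g_GR = g_GR, g_UPB = g_UPB, g_GRUBP = g_GRUBP,
                     m = p$m %||% 0),
       config = list(samples = as.list(config$samples_per_region),
                     sequence_length = config$sequence_length,
                     recombination_rate = config$recombination_rate,
                     mutation_rate = config$mutation_rate,
                     ancestry_seed = ancestry_seed,
                     mutation_seed = mutation_seed))
}

panel_from_sim <- function(sim, config) {
  counts <- config$samples_per_region
  labels <- rep(names(counts), counts)
  ids <- unlist(lapply(names(counts),
                       function(r) paste0(r, seq_len(counts[[r]]))))
  if (ncol(sim$haplotypes) == 0)
    sim$haplotypes <- matrix(0L, 2 * length(ids), 0)
  new_panel(sim$haplotypes, sim$positions, ids, labels,
            coords = coords_for(labels),
            sequence_length = config$sequence_length)
}

#' Simulate one dataset under the five-population demographic model
#'
#' Coalescent simulation under the split topology
#' (((G,R) at t_GR, (U,P,B) simultaneous at t_UPB) merging at t_GRUBP),
#' with symmetric migration `m` among the five terminal populations.
#' Effective sizes are haploid chromosome counts (halved for the diploid
#' simulator); times in years are rounded to generations. Only segregating
#' biallelic sites are returned.
#'
#' @param params a `pp_params` parameter vector (see [sample_priors()])
#' @param config a `pp_config` (see [model_config()])
#' @return a phased [new_panel()] object
#' @export
simulate_dataset <- function(params, config = model_config()) {
  sims <- run_coalsim(list(params_to_job(
    params, config, id = 1L,
    ancestry_seed = derive_seeds(config$seed, 1, stream = 1L),
    mutation_seed = derive_seeds(config$seed, 1, stream = 2L))))
  panel_from_sim(sims[[1]], config)
}

#' Simulate many datasets under the five-population model in one batch
#'
#' One simulator invocation for a list of parameter vectors; much faster
#' than repeated [simulate_dataset()] calls. Seeds are derived
#' deterministically from `seed`.
#'
#' @param params_list list of `pp_params`
#' @param config a `pp_config`
#' @param seed master seed for the batch
#' @return list of panels
#' @export
simulate_batch <- function(params_list, config = model_config(), seed = 1L) {
  n <- length(params_list)
  as_ <- derive_seeds(seed, n, stream = 1L)
  ms_ <- derive_seeds(seed, n, stream = 2L)
  jobs <- lapply(seq_len(n), function(i)
    params_to_job(params_list[[i]], config, i, as_[i], ms_[i]))
  sims <- run_coalsim(jobs)
  lapply(sims, panel_from_sim, config = config)
}

#' Simulate panmictic single-population panels
#'
#' Used for calibration checks (Watterson's estimator, panmictic nulls) and
#' single-deme diversity comparisons. `region_labels`, if given, assigns the
#' diploid samples to nominal regions (for null analyses where labels carry
#' no information).
#'
#' @param ne_hap effective size in chromosomes (haploid count)
#' @param n_dip number of diploid samples
#' @param config a `pp_config` (sample map ignored)
#' @param n_reps number of independent replicate panels
#' @param seed master seed
#' @param region_labels optional character vector of length `n_dip`
#' @return list of panels (length `n_reps`)
#' @export
simulate_single_pop <- function(ne_hap, n_dip, config = model_config(),
                                n_reps = 1L, seed = 1L,
                                region_labels = NULL) {
  as_ <- derive_seeds(seed, n_reps, stream = 3L)
  ms_ <- derive_seeds(seed, n_reps, stream = 4L)
  jobs <- lapply(seq_len(n_reps), function(i)
    list(id = i, mode = "single_pop", ne_hap = ne_hap, n_dip = n_dip,
         config = list(sequence_length = config$sequence_length,
                       recombination_rate = config$recombination_rate,
                       mutation_rate = config$mutation_rate,
                       ancestry_seed = as_[i], mutation_seed = ms_[i])))
  sims <- run_coalsim(jobs)
  labels <- region_labels %||% rep("POP", n_dip)
  if (length(labels) != n_dip)
    stop_pp("region_labels must have length n_dip", "pyrenpop_validation_error")
  ids <- paste0("S", seq_len(n_dip))
  ct <- region_coords()
  coords <- if (all(labels %in% ct$region)) coords_for(labels) else
    matrix(0, n_dip, 2)
  lapply(sims, function(s) {
    if (ncol(s$haplotypes) == 0) s$haplotypes <- matrix(0L, 2 * n_dip, 0)
    new_panel(s$haplotypes, s$positions, ids, labels, coords,
              config$sequence_length)
  })
}
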