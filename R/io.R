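# Configuration files and result serialization. Scenario configurations are
# stored as JSON with an explicit unit block; the loader validates units,
# rejects unknown keys and re-checks every class invariant. Trajectories are
# exported as CSV with unit-suffixed headers plus a JSON summary and a run
# manifest.

.canonicalUnits <- list(mass = "kg", energy = "MJ", time = "yr", skill = "TB")

.scenarioParamKeys <- c("Bb", "Br", "Bs", "Bk", "Ek", "Eb", "Er", "Es", "sk",
                        "kleiberCoef", "kleiberExp", "alpha", "gamma", "nu", "compBase",
                        "competenceForm", "cooperationForm", "challengeMix",
                        "p", "newborn")

#' Serialize a scenario configuration to JSON
#'
#' @param config a [ScenarioConfig-class].
#' @param path file to write.
#' @return the path, invisibly.
#' @export
saveConfig <- function(config, path) {
  obj <- list(
    type = "scenario", name = config@name, units = .canonicalUnits,
    parameters = list(
      Bb = config@Bb, Br = config@Br, Bs = config@Bs, Bk = config@Bk,
      Ek = config@Ek, Eb = config@Eb, Er = config@Er, Es = config@Es,
      sk = config@sk, kleiberCoef = config@kleiberCoef,
      kleiberExp = config@kleiberExp, alpha = config@alpha,
      gamma = config@gamma, nu = config@nu, compBase = config@compBase,
      competenceForm = config@competenceForm,
      cooperationForm = config@cooperationForm,
      challengeMix = config@challengeMix, p = config@p,
      newborn = config@newborn),
    grid = list(binWidth = config@grid@binWidth, maxAge = config@grid@maxAge))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a configuration file
#'
#' Reads and validates a scenario (or evolution-run) configuration. Units
#' must match the package's canonical units exactly (kg, MJ, yr, TB);
#' unknown parameter keys are rejected; all class invariants are enforced.
#'
#' @param path JSON file written by [saveConfig()] (or following its
#'   documented schema).
#' @param grid optional [AgeGrid-class] overriding the file's grid.
#' @return a [ScenarioConfig-class] or [EvolutionConfig-class].
#' @export
loadConfig <- function(path, grid = NULL) {
  if (!file.exists(path)) stop("no such configuration file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  type <- obj$type
  if (is.null(type)) stop("configuration lacks a 'type' field")
  if (type == "scenario") return(.loadScenario(obj, grid, path))
  if (type == "evolution") return(.loadEvolution(obj, grid, path))
  stop("unknown configuration type '", type, "'")
}

.loadScenario <- function(obj, grid, path) {
  if (!identical(lapply(obj$units, as.character), .canonicalUnits))
    stop("unit mismatch in ", path, ": expected kg/MJ/yr/TB")
  par <- obj$parameters
  unknown <- setdiff(names(par), .scenarioParamKeys)
  if (length(unknown))
    stop("unknown parameter key(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  missing <- setdiff(.scenarioParamKeys, names(par))
  if (length(missing))
    stop("missing parameter key(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  if (is.null(grid)) grid <- ageGrid(obj$grid$binWidth, obj$grid$maxAge)
  new("ScenarioConfig", name = as.character(obj$name),
      Bb = par$Bb, Br = par$Br, Bs = par$Bs, Bk = par$Bk, Ek = par$Ek,
      Eb = par$Eb, Er = par$Er, Es = par$Es, sk = par$sk,
      kleiberCoef = par$kleiberCoef, kleiberExp = par$kleiberExp,
      alpha = par$alpha, gamma = par$gamma, nu = par$nu,
      compBase = par$compBase,
      competenceForm = par$competenceForm,
      cooperationForm = par$cooperationForm,
      challengeMix = as.numeric(par$challengeMix), p = par$p,
      newborn = as.numeric(par$newborn), grid = grid)
}

.loadEvolution <- function(obj, grid, path) {
  sched <- lapply(obj$schedule, function(s) {
    sc <- if (is.character(s$scenario)) scenarioPreset(s$scenario, grid = grid)
          else .loadScenario(s$scenario, grid, path)
    list(time = s$time, scenario = sc)
  })
  evolutionConfig(schedule = sched,
                  Tend = obj$Tend %||% 500, iota = obj$iota %||% 2e4,
                  deltaTau = obj$deltaTau %||% 1,
                  sigmaMut = obj$sigmaMut %||% 1, mu = obj$mu %||% 0.01,
                  eta0 = obj$eta0, seed = obj$seed %||% 1L,
                  storeL = obj$storeL %||% c(1, 10, 100, 500))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.configHash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  saveConfig(config, tf)
  unname(tools::md5sum(tf))
}

#' Export a genotype or phenotype as CSV
#'
#' Columns carry explicit units: \code{age_yr, x_b_kg, x_r_kg, x_s_kg,
#' x_k_TB} for phenotypes and \code{age_yr, y_b, y_r, y_s} for genotypes.
#'
#' @param object a [Phenotype-class] or [Genotype-class].
#' @param path CSV file to write.
#' @return the path, invisibly.
#' @export
writeTraitsCSV <- function(object, path) {
  if (is(object, "Phenotype")) {
    df <- data.frame(age_yr = object@grid@ages,
                     x_b_kg = object@traits[, 1], x_r_kg = object@traits[, 2],
                     x_s_kg = object@traits[, 3], x_k_TB = object@traits[, 4])
  } else if (is(object, "Genotype")) {
    df <- data.frame(age_yr = object@grid@ages,
                     y_b = object@efforts[, 1], y_r = object@efforts[, 2],
                     y_s = object@efforts[, 3])
  } else stop("object must be a Phenotype or Genotype")
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a covariance (or effects) matrix in long form
#'
#' Long CSV with columns \code{row_trait, row_age_yr, col_trait, col_age_yr,
#' value}, age-major within trait, matching the heat-map ordering of the
#' covariance figures.
#'
#' @param mat square or rectangular block matrix in trait-major layout.
#' @param rowTraits,colTraits trait labels of the row/column blocks.
#' @param grid the [AgeGrid-class].
#' @param path CSV file to write.
#' @export
writeMatrixLongCSV <- function(mat, rowTraits, colTraits, grid, path) {
  n <- grid@nBins
  stopifnot(nrow(mat) == n * length(rowTraits),
            ncol(mat) == n * length(colTraits))
  rows <- expand.grid(row_age_yr = grid@ages, row_trait = rowTraits)
  cols <- expand.grid(col_age_yr = grid@ages, col_trait = colTraits)
  df <- data.frame(
    row_trait = rep(rows$row_trait, times = nrow(cols)),
    row_age_yr = rep(rows$row_age_yr, times = nrow(cols)),
    col_trait = rep(cols$col_trait, each = nrow(rows)),
    col_age_yr = rep(cols$col_age_yr, each = nrow(rows)),
    value = as.vector(mat))
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an evolutionary trajectory to disk
#'
#' Writes per-step phenotype, genotype and gradient CSVs, the diagnostics
#' table, covariance snapshots at the scheduled times, a JSON summary and a
#' run manifest (config hash, seed, package version, timestamps, file
#' inventory). The manifest is written first and finalized after all
#' outputs are on disk.
#'
#' @param trajectory an [EvoTrajectory-class].
#' @param outDir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
writeTrajectory <- function(trajectory, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ec <- trajectory@evoConfig
  grid <- .scenarioAt(ec@schedule, 0)@grid
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  manifestPath <- file.path(outDir, "manifest.json")
  manifest <- list(tool = "evodevoBrain",
                   version = as.character(utils::packageVersion("evodevoBrain")),
                   seed = ec@seed,
                   configHash = .configHash(.scenarioAt(ec@schedule, 0)),
                   scenarios = unique(trajectory@scenarioNames),
                   started = started, finished = NULL, files = list())
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- character()
  wide <- function(arr, prefix, cols) {
    nt <- dim(arr)[1]
    do.call(rbind, lapply(seq_len(nt), function(i) {
      df <- data.frame(tau = trajectory@tau[i], age_yr = grid@ages)
      m <- arr[i, , , drop = TRUE]
      for (j in seq_along(cols)) df[[cols[j]]] <- m[, j]
      df
    }))
  }
  wr <- function(df, name) {
    p <- file.path(outDir, name)
    utils::write.csv(format(df, digits = 17, trim = TRUE), p,
                     row.names = FALSE, quote = FALSE)
    files <<- c(files, name)
  }
  if (length(trajectory@tau)) {
    wr(wide(trajectory@phenotypes, "x",
            c("x_b_kg", "x_r_kg", "x_s_kg", "x_k_TB")), "phenotypes.csv")
    wr(wide(trajectory@genotypes, "y", c("y_b", "y_r", "y_s")),
       "genotypes.csv")
    wr(wide(trajectory@gradients, "g",
            c("dwdy_b", "dwdy_r", "dwdy_s")), "gradients.csv")
    wr(trajectory@diagnostics, "diagnostics.csv")
    for (nm in names(trajectory@Lsnapshots)) {
      blk <- trajectory@Lsnapshots[[nm]]
      p <- paste0("L_brain_follicle_tau", nm, ".csv")
      writeMatrixLongCSV(blk$brainFollicle, "x_b", "x_r", grid,
                         file.path(outDir, p))
      files <- c(files, p)
    }
    summ <- trajectory@diagnostics[, c("tau", "scenario", "adultBrain_kg",
                                       "adultBody_kg", "adultSkill_TB", "EQ",
                                       "angle_deg", "evolvability")]
    jsonlite::write_json(summ, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    files <- c(files, "summary.json")
  }
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  manifest$files <- as.list(files)
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(files, "manifest.json"))
}
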