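#' Long-format phenotype and fitness dataset
#'
#' Container for the two tables the joint model consumes: repeated
#' phenotype measures with their environmental states, and repeated fitness
#' measures.  Validates the documented schema and cross-references: every
#' individual in the fitness table must appear in the phenotype table, and
#' all numeric cells must be finite.
#'
#' @param phenotype Data frame with columns `individual_id`, `rep`, `x`,
#'   `z`.
#' @param fitness Data frame with columns `individual_id`, `rep`, `W`.
#' @return An object of class `"rn_data"`.
#' @examples
#' rn_data(data.frame(individual_id = 1, rep = 1, x = 0, z = 1),
#'         data.frame(individual_id = 1, rep = 1, W = 1))
#' @export
rn_data <- function(phenotype, fitness) {
  need_z <- c("individual_id", "rep", "x", "z")
  need_w <- c("individual_id", "rep", "W")
  miss_z <- setdiff(need_z, names(phenotype))
  if (length(miss_z))
    stop("phenotype table is missing column(s): ",
         paste(miss_z, collapse = ", "), call. = FALSE)
  miss_w <- setdiff(need_w, names(fitness))
  if (length(miss_w))
    stop("fitness table is missing column(s): ",
         paste(miss_w, collapse = ", "), call. = FALSE)
  for (col in c("x", "z")) {
    if (!is.numeric(phenotype[[col]]) || any(!is.finite(phenotype[[col]])))
      stop("phenotype column '", col, "' must be finite numeric",
           call. = FALSE)
  }
  if (!is.numeric(fitness$W) || any(!is.finite(fitness$W)))
    stop("fitness column 'W' must be finite numeric", call. = FALSE)
  orphan <- setdiff(unique(fitness$individual_id),
                    unique(phenotype$individual_id))
  if (length(orphan))
    stop("fitness individual(s) absent from phenotype table: ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  structure(list(phenotype = phenotype[need_z], fitness = fitness[need_w]),
            class = "rn_data")
}

#' @export
print.rn_data <- function(x, ...) {
  n_id <- length(unique(x$phenotype$individual_id))
  cat("Reaction-norm selection dataset\n")
  cat(sprintf("  %d individuals; %d phenotype rows; %d fitness rows\n",
              n_id, nrow(x$phenotype), nrow(x$fitness)))
  invisible(x)
}

#' Read a dataset from two CSV files
#'
#' Expects the documented schemas (`individual_id,rep,x,z` and
#' `individual_id,rep,W`), comma-separated with a header row.  Errors name
#' the missing column, the unknown individual, or the first non-numeric
#' cell.
#'
#' @param phenotype_path,fitness_path Paths to the CSV files.
#' @return An [rn_data()] object.
#' @export
read_dataset <- function(phenotype_path, fitness_path) {
  for (p in c(phenotype_path, fitness_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  ph <- utils::read.csv(phenotype_path)
  fi <- utils::read.csv(fitness_path)
  for (col in intersect(c("x", "z"), names(ph))) {
    if (!is.numeric(ph[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(ph[[col]]))))[1]
      stop("non-numeric value in phenotype column '", col, "', row ", bad,
           call. = FALSE)
    }
  }
  if ("W" %in% names(fi) && !is.numeric(fi$W)) {
    bad <- which(is.na(suppressWarnings(as.numeric(fi$W))))[1]
    stop("non-numeric value in fitness column 'W', row ", bad,
         call. = FALSE)
  }
  rn_data(ph, fi)
}

#' Write a dataset to two CSV files
#'
#' @param data An [rn_data()] object.
#' @param dir Output directory (created if needed).
#' @param prefix Optional filename prefix.
#' @return Invisibly, the two paths written (`phenotype`, `fitness`).
#' @export
write_dataset <- function(data, dir, prefix = "") {
  stopifnot(inherits(data, "rn_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(phenotype = file.path(dir, paste0(prefix, "phenotype.csv")),
             fitness = file.path(dir, paste0(prefix, "fitness.csv")))
  utils::write.csv(data$phenotype, paths["phenotype"], row.names = FALSE)
  utils::write.csv(data$fitness, paths["fitness"], row.names = FALSE)
  invisible(paths)
}

## serialize a sim_truth to JSON (and back) for reproducible runs
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  x <- list(pop = truth$pop[c("mu0", "beta_x", "sigma0", "sds")],
            corr = truth$pop$corr,
            coefs = truth$coefs[c("b", "q", "W0", "sd_W0", "delta")],
            deviations = truth$deviations,
            w0 = truth$w0,
            true_beta = truth$true_beta,
            true_gamma = truth$true_gamma,
            mean_abs_corr = truth$mean_abs_corr,
            config = unclass(truth$config))
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(sim_config, x$config)
  corr <- matrix(unlist(x$corr), 3, 3)
  pop <- population_rn(x$pop$mu0, x$pop$beta_x, x$pop$sigma0, x$pop$sds, corr)
  coefs <- selection_coefs(x$coefs$b, x$coefs$q, x$coefs$W0, x$coefs$sd_W0,
                           x$coefs$delta)
  dev <- matrix(unlist(x$deviations), ncol = 3)
  colnames(dev) <- c("mu0j", "beta_xj", "sigma0j")
  structure(list(pop = pop, coefs = coefs,
                 P = assemble_P(pop$sds, corr),
                 deviations = dev, w0 = x$w0,
                 true_beta = x$true_beta,
                 true_gamma = matrix(unlist(x$true_gamma), 3, 3),
                 mean_abs_corr = x$mean_abs_corr, config = cfg),
            class = "sim_truth")
}
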