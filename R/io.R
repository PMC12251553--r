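# Schema-checked readers and writers. Trajectory CSVs use the plant-log
# convention (feed rates in L/min, unit-suffixed headers); the in-memory
# trajectory keeps feeds in L/h, consistent with the hourly model units.

.TRAJ_CSV_COLS <- c("t_h", "X_gL", "S_gL", "E_UmL", "CL", "H_molL", "V_L",
                    "fC_Lmin", "fN_Lmin", "fM_Lmin", "fA_Lmin",
                    "Tw_C", "Sa_rpm", "Fa_Lmin")
.FEED_LH <- c("fC_Lh", "fN_Lh", "fM_Lh", "fA_Lh")
.FEED_LMIN <- c("fC_Lmin", "fN_Lmin", "fM_Lmin", "fA_Lmin")

#' Write a trajectory to CSV
#'
#' Columns follow the plant-log schema (`t_h`, state columns with unit
#' suffixes, feed rates in L/min, environment columns).
#'
#' @param traj a `ferm_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  out <- as.data.frame(traj)
  for (i in seq_along(.FEED_LH)) {
    out[[.FEED_LMIN[i]]] <- out[[.FEED_LH[i]]] / 60
    out[[.FEED_LH[i]]] <- NULL
  }
  out <- out[, .TRAJ_CSV_COLS]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory CSV
#'
#' Validates the header against the schema (every missing column is named
#' in the error), requires strictly increasing time, and converts feed
#' rates from L/min to the model's L/h.
#'
#' @param path CSV file path.
#' @return A `ferm_trajectory`.
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE)
  miss <- setdiff(.TRAJ_CSV_COLS, names(raw))
  if (length(miss))
    stop("trajectory CSV is missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(diff(raw$t_h) <= 0)) stop("time column t_h must be strictly increasing")
  for (i in seq_along(.FEED_LH)) {
    raw[[.FEED_LH[i]]] <- raw[[.FEED_LMIN[i]]] * 60
    raw[[.FEED_LMIN[i]]] <- NULL
  }
  ord <- c("t_h", "X_gL", "S_gL", "E_UmL", "CL", "H_molL", "V_L",
           .FEED_LH, "Tw_C", "Sa_rpm", "Fa_Lmin")
  raw <- raw[, ord]
  structure(raw, class = c("ferm_trajectory", "data.frame"))
}

#' Write / read a soft-sensor dataset CSV
#'
#' @param data a `soft_sensor_dataset`.
#' @param path file path.
#' @return `path` (write) or the dataset (read).
#' @export
write_dataset_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, check.names = FALSE)
  miss <- setdiff(c("t_h", .FEATURE_NAMES), names(d))
  if (length(miss))
    stop("dataset CSV is missing column(s): ", paste(miss, collapse = ", "))
  class(d) <- c("soft_sensor_dataset", "data.frame")
  d
}

#' Persist a fitted soft sensor as JSON
#'
#' Stores the architecture, all weights and biases, the frozen
#' normalisation statistics and the training configuration at full
#' numeric precision, so a reloaded model predicts identically.
#'
#' @param model a fitted [soft_sensor()].
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  ser_net <- function(p) list(layer_dims = p$layer_dims,
                              W = p$W, b = p$b)
  obj <- list(version = "1",
              feature_names = model$feature_names,
              networks = lapply(model$networks, ser_net),
              feature_stats = unclass(model$feature_stats),
              target_stats = unclass(model$target_stats),
              config = model$config)
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  de_net <- function(n) {
    dims <- as.integer(n$layer_dims)
    W <- lapply(seq_along(n$W), function(l) {
      w <- n$W[[l]]
      matrix(as.numeric(t(as.matrix(w))), dims[l + 1], dims[l], byrow = TRUE)
    })
    structure(list(W = W, b = lapply(n$b, as.numeric), layer_dims = dims),
              class = "fcnn_params")
  }
  restats <- function(s) structure(
    list(offset = unlist(s$offset), scale = unlist(s$scale),
         method = s$method), class = "norm_stats")
  nets <- lapply(obj$networks, de_net)
  structure(list(networks = nets,
                 feature_stats = restats(obj$feature_stats),
                 target_stats = restats(obj$target_stats),
                 feature_names = obj$feature_names,
                 data = NULL, loss = NULL, config = obj$config),
            class = "soft_sensor")
}

#' Write an evaluation report as JSON
#'
#' @param ev a `sensor_evaluation`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_evaluation_json <- function(ev, path) {
  obj <- list(mse = as.data.frame(ev$mse),
              median_rel_err = as.list(ev$median_rel_err))
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE,
                              na = "null"), path)
  invisible(path)
}

.PIPELINE_SECTIONS <- c("version", "seed", "model", "kinetics",
                        "preprocessing", "network", "optimizer", "split",
                        "campaign")

#' Read a pipeline configuration YAML
#'
#' Top-level sections are `version`, `seed`, `model`, `kinetics`,
#' `preprocessing`, `network`, `optimizer`, `split`, `campaign`; unknown
#' keys are rejected so typos fail loudly.
#'
#' @param path YAML file path.
#' @return Named list of configuration sections.
#' @export
read_pipeline_yaml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .PIPELINE_SECTIONS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg
}

#' @rdname read_pipeline_yaml
#' @param cfg configuration list to write.
#' @export
write_pipeline_yaml <- function(cfg, path) {
  unknown <- setdiff(names(cfg), .PIPELINE_SECTIONS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
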