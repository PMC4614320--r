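sidecar_path <- function(path) paste0(path, ".meta.json")

write_sidecar <- function(path, meta) {
  meta$package_version <- as.character(utils::packageVersion("lesionsim"))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
}

events_to_df <- function(events) {
  if (!length(events)) {
    return(data.frame(time = numeric(0), nodes = character(0)))
  }
  data.frame(time = vapply(events, function(e) e$time, numeric(1)),
             nodes = vapply(events, function(e) paste(e$nodes, collapse = ","),
                            character(1)))
}

#' Write a disability trace to a delimited file
#'
#' Writes the trace as a tab-separated table plus a JSON metadata sidecar
#' (`<path>.meta.json`) holding the seed, schedule, event log, and damage
#' onset, sufficient to re-run the trial bit-identically. Three-layer traces
#' use columns `t, H, eta, nodes_removed_cum, phase`; homeostasis traces use
#' `morph_step, disability, alive_count, mean_F, total_synapses`. Two writes
#' of the same trace produce identical bytes.
#'
#' @param trace a `disability_trace`.
#' @param path output path for the table.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  out <- as.data.frame(trace)
  model <- attr(trace, "model") %||% "three_layer"
  if (model == "three_layer") {
    names(out)[names(out) == "time"] <- "t"
    names(out)[names(out) == "disability"] <- "H"
  } else {
    names(out)[names(out) == "time"] <- "morph_step"
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sched <- attr(trace, "schedule")
  params_echo <- attr(trace, "config") %||% attr(trace, "params")
  write_sidecar(path, list(
    kind = "trace", model = model,
    seed = attr(trace, "seed"),
    damage_start = attr(trace, "damage_start"),
    schedule = if (!is.null(sched)) unclass(sched) else NULL,
    params = params_echo,
    events = events_to_df(attr(trace, "events") %||% list())
  ))
  invisible(path)
}

#' Read a disability trace written by [write_trace()]
#'
#' @param path path to the table file.
#' @return a `disability_trace` with metadata restored from the sidecar.
#' @export
read_trace <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  meta <- if (file.exists(sidecar_path(path))) {
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  } else {
    list()
  }
  model <- meta$model %||% if ("morph_step" %in% names(tab)) "homeostasis" else "three_layer"
  names(tab)[names(tab) %in% c("t", "morph_step")] <- "time"
  names(tab)[names(tab) == "H"] <- "disability"
  attr(tab, "model") <- model
  attr(tab, "seed") <- meta$seed
  attr(tab, "damage_start") <- meta$damage_start
  if (!is.null(meta$events) && NROW(meta$events)) {
    attr(tab, "events") <- lapply(seq_len(nrow(meta$events)), function(i) {
      list(time = meta$events$time[i],
           nodes = as.integer(strsplit(meta$events$nodes[i], ",")[[1]]))
    })
  } else {
    attr(tab, "events") <- list()
  }
  class(tab) <- c("disability_trace", class(tab))
  tab
}

#' Write a MAoD grid to delimited files
#'
#' Writes the long per-trial table (`axis1, axis2, seed, maod`) to `path`, a
#' per-cell summary (mean MAoD) to `<path minus extension>_summary.<ext>`,
#' and a JSON metadata sidecar. Byte-stable for identical inputs.
#'
#' @param grid a `maod_grid`.
#' @param path output path for the long table.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  utils::write.table(grid$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ext <- tools::file_ext(path)
  base <- tools::file_path_sans_ext(path)
  spath <- if (nzchar(ext)) paste0(base, "_summary.", ext) else paste0(base, "_summary")
  utils::write.table(grid$summary, spath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_sidecar(path, list(
    kind = "grid", axis1_name = grid$axis1_name, axis1 = grid$axis1,
    axis2_name = grid$axis2_name, axis2 = grid$axis2, n_seeds = grid$n_seeds,
    summary_path = basename(spath)
  ))
  invisible(path)
}

#' Read a MAoD grid written by [write_grid()]
#'
#' @param path path to the long table.
#' @return a `maod_grid`.
#' @export
read_grid <- function(path) {
  vals <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  names(vals)[1:2] <- c("axis1", "axis2")
  new_maod_grid(meta$axis1_name, meta$axis1, meta$axis2_name, meta$axis2,
                vals, meta$n_seeds)
}
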