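# Batch orchestration: map a plate directory of TIFFs onto per-well,
# per-timepoint metrics with optional saved intermediates.

#' Batch run configuration
#'
#' @param input_dir directory of TIFF images.
#' @param output_dir directory for the results CSV and intermediates.
#' @param filename_regex Perl regex with named capture groups `well`, `time`,
#'   `z` (optional) and `channel` (optional) mapping filenames to metadata.
#'   Files with multiple `z` values per (well, time, channel) group are
#'   assembled into Z-stacks (ascending z = top first).
#' @param pixel_size_um,z_step_um physical units (always user-supplied).
#' @param lambda coverage threshold multiplier (see
#'   [threshold_foreground()]).
#' @param invasion_threshold per-plane classification threshold.
#' @param morse a [morse_params()].
#' @param analyses subset of `c("coverage", "vessels", "invasion")`.
#' @param projection_method method used to project stacks for 2D analyses.
#' @param seed integer seed for every stochastic stage.
#' @param save_intermediates write per-image visualization PNGs.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input_dir, output_dir = file.path(input_dir, "out"),
                       filename_regex =
                         "^(?<well>[A-Za-z0-9]+)_t(?<time>[0-9]+)(?:_z(?<z>[0-9]+))?(?:_(?<channel>[A-Za-z0-9]+))?\\.tiff?$",
                       pixel_size_um = 1, z_step_um = 1, lambda = 0,
                       invasion_threshold = 0.5, morse = morse_params(),
                       analyses = c("coverage", "vessels", "invasion"),
                       projection_method = "focus_stack",
                       seed = 1L, save_intermediates = FALSE) {
  stopifnot(pixel_size_um > 0, z_step_um > 0,
            all(analyses %in% c("coverage", "vessels", "invasion")))
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 filename_regex = filename_regex,
                 pixel_size_um = pixel_size_um, z_step_um = z_step_um,
                 lambda = lambda, invasion_threshold = invasion_threshold,
                 morse = morse, analyses = analyses,
                 projection_method = projection_method,
                 seed = seed, save_intermediates = save_intermediates),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Fields mirror the arguments of [run_config()]; missing fields keep their
#' defaults.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read config files", call. = FALSE)
  }
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$morse)) vals$morse <- do.call(morse_params, vals$morse)
  do.call(run_config, vals)
}

#' Parse plate filenames into metadata
#'
#' @param files character vector of file names (basenames are matched).
#' @param regex Perl regex with named groups as in [run_config()].
#' @return A list: `parsed` (tibble `file`, `well`, `time`, `z`, `channel`)
#'   and `skipped` (unparseable file names).
#' @export
parse_filenames <- function(files, regex) {
  base <- basename(files)
  m <- regexpr(regex, base, perl = TRUE)
  ok <- m != -1
  parsed <- NULL
  if (any(ok)) {
    st <- attr(m, "capture.start")[ok, , drop = FALSE]
    ln <- attr(m, "capture.length")[ok, , drop = FALSE]
    nm <- attr(m, "capture.names")
    grab <- function(name) {
      if (!name %in% nm) return(rep(NA_character_, sum(ok)))
      j <- match(name, nm)
      out <- substr(base[ok], st[, j], st[, j] + ln[, j] - 1)
      out[ln[, j] == 0] <- NA_character_
      out
    }
    parsed <- tibble::tibble(
      file = files[ok],
      well = grab("well"),
      time = grab("time"),
      z = suppressWarnings(as.integer(grab("z"))),
      channel = grab("channel"))
  } else {
    parsed <- tibble::tibble(file = character(), well = character(),
                             time = character(), z = integer(),
                             channel = character())
  }
  list(parsed = parsed, skipped = files[!ok])
}

read_gray_tiff <- function(path) {
  pg <- tiff::readTIFF(path)
  if (length(dim(pg)) == 3) pg <- pg[, , 1]
  m <- as.matrix(pg)
  dimnames(m) <- NULL
  m
}

#' Run the batch pipeline over a plate directory
#'
#' One row per (well, time, channel, metric). Coverage runs on the 2D
#' projection of each group; vessel quantification runs on the learned
#' segmentation of the projection when `seg_model` is supplied, or on the
#' Sato path when the group is a Z-stack; invasion depth runs on Z-stack
#' groups when `invasion_model` is supplied. Failures are per-group: the
#' failing well is logged as a warning and the run continues.
#'
#' @param config a [run_config()].
#' @param seg_model optional vessel segmentation model (see
#'   [predict_map()]).
#' @param invasion_model optional invasion classifier (see
#'   [predict_invasion()]).
#' @return A tibble of metrics, also written to
#'   `file.path(output_dir, "results.csv")`. Skipped (unparseable) files are
#'   attached as attribute `"skipped"` and written to `skipped_files.csv`
#'   when present.
#' @export
run_batch <- function(config, seg_model = NULL, invasion_model = NULL) {
  stopifnot(inherits(config, "run_config"))
  files <- list.files(config$input_dir, pattern = "\\.tiff?$",
                      ignore.case = TRUE, full.names = TRUE)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  pf <- parse_filenames(files, config$filename_regex)
  if (length(pf$skipped) > 0) {
    utils::write.csv(data.frame(file = basename(pf$skipped)),
                     file.path(config$output_dir, "skipped_files.csv"),
                     row.names = FALSE)
  }
  rows <- list()
  if (nrow(pf$parsed) == 0) {
    warning("no parseable images found in ", config$input_dir, call. = FALSE)
  } else {
    groups <- dplyr::group_split(dplyr::group_by(
      pf$parsed, .data$well, .data$time, .data$channel))
    for (g in groups) {
      g <- dplyr::arrange(g, .data$z)
      key <- sprintf("%s_t%s%s", g$well[1], g$time[1],
                     if (is.na(g$channel[1])) "" else paste0("_", g$channel[1]))
      res <- tryCatch(
        analyze_group(g, key, config, seg_model, invasion_model),
        error = function(e) {
          warning(sprintf("group %s failed: %s", key, conditionMessage(e)),
                  call. = FALSE)
          NULL
        })
      if (!is.null(res)) rows[[length(rows) + 1]] <- res
    }
  }
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else
    tibble::tibble(well = character(), time = character(),
                   channel = character(), analysis = character(),
                   metric = character(), value = numeric())
  out <- dplyr::arrange(out, .data$well, .data$time, .data$channel,
                        .data$analysis, .data$metric)
  utils::write.csv(out, file.path(config$output_dir, "results.csv"),
                   row.names = FALSE)
  attr(out, "skipped") <- basename(pf$skipped)
  out
}

analyze_group <- function(g, key, config, seg_model, invasion_model) {
  is_stack <- nrow(g) > 1 && !all(is.na(g$z))
  planes <- lapply(g$file, read_gray_tiff)
  stack <- zstack(planes, z_step_um = config$z_step_um,
                  pixel_size_um = config$pixel_size_um)
  proj <- if (is_stack) {
    unclass(project_zstack(stack, config$projection_method))
  } else planes[[1]]
  attr(proj, "method") <- NULL
  attr(proj, "n_planes") <- NULL
  class(proj) <- NULL
  dim(proj) <- dim(planes[[1]])

  rows <- list()
  viz <- list(image = proj)
  meta <- function(analysis, metric, value) {
    tibble::tibble(well = g$well[1], time = g$time[1],
                   channel = g$channel[1], analysis = analysis,
                   metric = metric, value = value)
  }
  if ("coverage" %in% config$analyses) {
    cov <- analyze_coverage(proj, lambda = config$lambda,
                            seed = config$seed, keep_mask = TRUE)
    rows[[length(rows) + 1]] <- dplyr::bind_rows(
      meta("coverage", "fraction", cov$fraction),
      meta("coverage", "cell_area_px", cov$cell_area_px),
      meta("coverage", "well_area_px", cov$well_area_px))
    viz$mask <- attr(cov, "mask")
  }
  if ("vessels" %in% config$analyses &&
      (!is.null(seg_model) || is_stack)) {
    vmap <- if (!is.null(seg_model)) {
      refine_probability_map(predict_tiled(seg_model, proj))
    } else {
      sato_vesselness_2d(stack)
    }
    va <- analyze_vessels(vmap, config$morse, config$pixel_size_um)
    st <- va$stats
    rows[[length(rows) + 1]] <- dplyr::bind_rows(
      meta("vessels", "branch_count", st$branch_count),
      meta("vessels", "total_length_um", st$total_length_um),
      meta("vessels", "mean_branch_length_um", st$mean_branch_length_um))
    viz$refined <- vmap
    viz$graph <- va$graph
    viz$barcode <- va$barcode
  }
  if ("invasion" %in% config$analyses && is_stack &&
      !is.null(invasion_model)) {
    call <- classify_stack(invasion_model, stack,
                           threshold = config$invasion_threshold)
    depth <- compute_invasion_depth(call, config$z_step_um)
    rows[[length(rows) + 1]] <- dplyr::bind_rows(
      meta("invasion", "depth_um", depth$depth_um),
      meta("invasion", "deepest_invaded_index",
           ifelse(is.na(depth$deepest_invaded_index), -1,
                  depth$deepest_invaded_index)))
  }
  if (config$save_intermediates) {
    save_visualizations(viz, config$output_dir, prefix = key)
  }
  dplyr::bind_rows(rows)
}

#' Save stage visualizations as PNGs
#'
#' Writes, for one image group, whichever intermediates are present in
#' `items`: the thresholded coverage mask (`<prefix>_mask.png`), the refined
#' vesselness map (`<prefix>_refined.png`), the graph overlay
#' (`<prefix>_graph.png`), and the barcode plot (`<prefix>_barcode.png`).
#' File names are deterministic.
#'
#' @param items named list with any of `image`, `mask`, `refined`, `graph`
#'   (an [embedded_graph()]), `barcode`.
#' @param out_dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Character vector of files written, invisibly.
#' @export
save_visualizations <- function(items, out_dir, prefix = "image") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output dir", call. = FALSE)
  written <- character()
  wpng <- function(mat, path) {
    png::writePNG(rescale01(mat * 1), path)
    written <<- c(written, path)
  }
  if (!is.null(items$mask)) {
    wpng(items$mask, file.path(out_dir, paste0(prefix, "_mask.png")))
  }
  if (!is.null(items$refined)) {
    wpng(unclass(items$refined),
         file.path(out_dir, paste0(prefix, "_refined.png")))
  }
  if (!is.null(items$graph)) {
    p <- autoplot(items$graph, image = items$image)
    f <- file.path(out_dir, paste0(prefix, "_graph.png"))
    ggplot2::ggsave(f, p, width = 6, height = 6, dpi = 120)
    written <- c(written, f)
  }
  if (!is.null(items$barcode) && nrow(items$barcode) > 0) {
    p <- autoplot(items$barcode)
    f <- file.path(out_dir, paste0(prefix, "_barcode.png"))
    ggplot2::ggsave(f, p, width = 6, height = 4, dpi = 120)
    written <- c(written, f)
  }
  invisible(written)
}
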