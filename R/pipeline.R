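# End-to-end pipeline: data (read or simulate) -> indices -> multiplex
# metrics -> biography models, with all artifacts written as plain files so
# every reported number is traceable to a CSV/JSON file in the bundle.

.pipeline_keys <- c("scans", "biographies", "synthetic", "weight", "omega",
                    "alpha", "out_dir", "seed", "log_level")

#' Pipeline configuration
#'
#' @param scans,biographies Paths to input CSVs, or `NULL` to simulate.
#' @param synthetic List of [synth_config()] arguments (used when `scans` is
#'   `NULL`).
#' @param weight Edge weight mode for network construction: `"weighted"`
#'   (layer-max-normalized) or `"index"`.
#' @param omega Interlayer coupling for versatility.
#' @param alpha Significance level for the model stage.
#' @param out_dir Output bundle directory.
#' @param seed Integer seed governing all randomness.
#' @param log_level `"info"` or `"quiet"`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scans = NULL, biographies = NULL,
                            synthetic = list(), weight = c("weighted", "index"),
                            omega = 1, alpha = 0.05, out_dir = "results",
                            seed = 1L, log_level = c("info", "quiet")) {
  structure(list(scans = scans, biographies = biographies,
                 synthetic = synthetic, weight = match.arg(weight),
                 omega = omega, alpha = alpha, out_dir = out_dir,
                 seed = as.integer(seed), log_level = match.arg(log_level)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' The parsed configuration round-trips to an identical file; unknown keys
#' are rejected.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .pipeline_keys)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  out <- unclass(config)
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Sequences data loading (or simulation), index computation, multiplex
#' construction and metrics, and the five biography-effect models, writing
#' every table into the output bundle. Deterministic given (inputs, seed).
#' Any stage error aborts with the stage name attached.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the report bundle (list of all computed objects).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (config$log_level == "info") message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  wcsv <- function(x, name) utils::write.csv(
    x, file.path(out_dir, name), row.names = FALSE)

  bundle <- list(config = config)
  stage("data", {
    if (is.null(config$scans)) {
      say("simulating scan data (seed ", config$seed, ")")
      scfg <- do.call(synth_config,
                      c(config$synthetic,
                        list(seed = config$seed)[!("seed" %in%
                                                     names(config$synthetic))]))
      roster <- make_roster(scfg)
      truth <- dyad_state_probs(roster, scfg)
      records <- simulate_scans(truth)
      jsonlite::write_json(truth$probs, file.path(out_dir, "ground_truth.json"),
                           digits = NA)
      bundle$truth <- truth
    } else {
      say("reading scan data from ", config$scans)
      roster <- read_biographies(config$biographies)
      records <- read_scans(config$scans, roster)
    }
    utils::write.csv(as.data.frame(roster), file.path(out_dir,
                                                      "biographies.csv"),
                     row.names = FALSE)
    write_scans(records, file.path(out_dir, "scans.csv"))
    bundle$roster <- roster
    bundle$records <- records
  })
  stage("indices", {
    say("computing dyadic interaction indices")
    excl <- validate_exclusivity(bundle$records)
    if (nrow(excl) > 0L) {
      warning(nrow(excl), " (dyad, scan) exclusivity violations; see ",
              "exclusivity_report.csv", call. = FALSE)
      wcsv(excl, "exclusivity_report.csv")
    }
    idx <- normalize_weighted(compute_indices(bundle$records, bundle$roster))
    wcsv(as.data.frame(idx), "index_long.csv")
    bundle$indices <- idx
  })
  stage("networks", {
    groups <- unique(bundle$roster$group)
    nets <- lapply(groups, function(g)
      build_multiplex(bundle$indices, g, weight = config$weight))
    names(nets) <- groups
    dens <- do.call(rbind, lapply(groups, function(g) {
      d <- vapply(nets[[g]]$layers, layer_density, numeric(1))
      data.frame(group = g, layer = c(names(d), "multiplex"),
                 density = c(d, multiplex_density(nets[[g]])),
                 stringsAsFactors = FALSE)
    }))
    wcsv(dens, "density.csv")
    for (g in groups) {
      for (l in names(nets[[g]]$layers)) {
        utils::write.csv(nets[[g]]$layers[[l]],
                         file.path(out_dir, sprintf("matrix_%s_%s.csv", g, l)))
      }
      utils::write.csv(edge_overlap_matrix(nets[[g]]),
                       file.path(out_dir, sprintf("overlap_%s.csv", g)))
      red <- reducibility(nets[[g]])
      utils::write.csv(red$jsd_matrix,
                       file.path(out_dir, sprintf("jsd_%s.csv", g)))
      wcsv(data.frame(n_layers = as.integer(names(red$relative_entropy)),
                      relative_entropy = unname(red$relative_entropy)),
           sprintf("reducibility_curve_%s.csv", g))
      wcsv(red$merge_sequence, sprintf("reducibility_merges_%s.csv", g))
      rep_g <- rank_report(nets[[g]], omega = config$omega)
      wcsv(data.frame(node = rownames(rep_g$scores),
                      as.data.frame(rep_g$scores), check.names = FALSE),
           sprintf("centrality_scores_%s.csv", g))
      wcsv(data.frame(node = rownames(rep_g$ranks),
                      as.data.frame(rep_g$ranks), check.names = FALSE),
           sprintf("centrality_ranks_%s.csv", g))
      bundle$reducibility[[g]] <- red
      bundle$ranks[[g]] <- rep_g
      bundle$overlap[[g]] <- edge_overlap_matrix(nets[[g]])
      bundle$global_overlap[[g]] <- global_edge_overlap(nets[[g]])
    }
    bundle$networks <- nets
    bundle$density <- dens
  })
  stage("models", {
    say("fitting biography-effect mixed models")
    dyad <- build_dyad_table(bundle$roster, bundle$indices)
    wcsv(dyad, "dyad_table.csv")
    fits <- fit_all_models(dyad, alpha = config$alpha)
    summaries <- lapply(fits, function(f) {
      if (isTRUE(f$degenerate)) return(list(response = f$response,
                                            degenerate = TRUE))
      list(response = f$response, degenerate = FALSE,
           lrt = f$lrt, singular = f$singular,
           anova = cbind(term = rownames(f$anova), as.data.frame(f$anova)),
           vif = as.list(f$vif))
    })
    jsonlite::write_json(summaries, file.path(out_dir, "model_results.json"),
                         auto_unbox = TRUE, digits = NA)
    bundle$dyad_table <- dyad
    bundle$models <- fits
  })
  manifest <- list(
    package = "panmux",
    package_version = as.character(utils::packageVersion("panmux")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    layer_names = .layer_names,
    weight = config$weight, omega = config$omega, alpha = config$alpha,
    seed = config$seed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  bundle$manifest <- manifest
  say("pipeline complete: ", out_dir)
  invisible(bundle)
}

#' Render report plots from a pipeline bundle directory
#'
#' Heatmaps of the edge-overlap and Jensen-Shannon distance matrices, the
#' reducibility curve, and a per-ring rank table, one PNG per group. Plotting
#' failures degrade to warnings; the underlying data files are already
#' written by [run_pipeline()].
#'
#' @param out_dir A pipeline output directory.
#' @return Invisibly, the paths of the written images.
#' @export
plot_reports <- function(out_dir) {
  paths <- character(0)
  heat <- function(mat_file, png_file, title, low_high) {
    m <- utils::read.csv(file.path(out_dir, mat_file), row.names = 1L,
                         check.names = FALSE)
    df <- data.frame(row = rep(rownames(m), times = ncol(m)),
                     col = rep(colnames(m), each = nrow(m)),
                     value = unlist(m, use.names = FALSE))
    p <- ggplot2::ggplot(df, ggplot2::aes(col, row,
                                          fill = value)) +
      ggplot2::geom_tile() +
      ggplot2::geom_text(ggplot2::aes(label = round(value, 2)),
                         size = 3) +
      ggplot2::scale_fill_gradient(low = low_high[1L], high = low_high[2L]) +
      ggplot2::labs(title = title, x = NULL, y = NULL) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                         hjust = 1))
    ggplot2::ggsave(file.path(out_dir, png_file), p, width = 6, height = 5)
    file.path(out_dir, png_file)
  }
  groups <- sub("^overlap_(.*)\\.csv$", "\\1",
                list.files(out_dir, pattern = "^overlap_.*\\.csv$"))
  for (g in groups) {
    paths <- c(paths, tryCatch({
      c(heat(sprintf("overlap_%s.csv", g), sprintf("overlap_%s.png", g),
             paste("Edge overlap,", g), c("white", "darkgreen")),
        heat(sprintf("jsd_%s.csv", g), sprintf("jsd_%s.png", g),
             paste("Jensen-Shannon distance,", g), c("white", "darkred")))
    }, error = function(e) {
      warning("heatmap rendering failed for group ", g, ": ",
              conditionMessage(e), call. = FALSE)
      character(0)
    }))
    paths <- c(paths, tryCatch({
      cu <- utils::read.csv(file.path(out_dir,
                                      sprintf("reducibility_curve_%s.csv", g)))
      p <- ggplot2::ggplot(cu, ggplot2::aes(n_layers,
                                            relative_entropy)) +
        ggplot2::geom_line() + ggplot2::geom_point() +
        ggplot2::scale_x_reverse(breaks = cu$n_layers) +
        ggplot2::labs(title = paste("Reducibility,", g),
                      x = "number of layers", y = "relative entropy") +
        ggplot2::theme_minimal()
      f <- file.path(out_dir, sprintf("reducibility_%s.png", g))
      ggplot2::ggsave(f, p, width = 6, height = 4)
      f
    }, error = function(e) {
      warning("curve rendering failed for group ", g, ": ",
              conditionMessage(e), call. = FALSE)
      character(0)
    }))
    paths <- c(paths, tryCatch({
      rk <- utils::read.csv(file.path(out_dir,
                                      sprintf("centrality_ranks_%s.csv", g)),
                            check.names = FALSE)
      long <- stats::reshape(rk, direction = "long",
                             varying = setdiff(names(rk), "node"),
                             v.names = "rank", timevar = "ring",
                             times = setdiff(names(rk), "node"))
      p <- ggplot2::ggplot(long, ggplot2::aes(ring, node,
                                              fill = rank)) +
        ggplot2::geom_tile() +
        ggplot2::geom_text(ggplot2::aes(label = rank), size = 3) +
        ggplot2::scale_fill_gradient(low = "darkgreen", high = "white") +
        ggplot2::labs(title = paste("Centrality ranks,", g), x = NULL,
                      y = NULL) +
        ggplot2::theme_minimal() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                           hjust = 1))
      f <- file.path(out_dir, sprintf("ranks_%s.png", g))
      ggplot2::ggsave(f, p, width = 7, height = 4)
      f
    }, error = function(e) {
      warning("rank-table rendering failed for group ", g, ": ",
              conditionMessage(e), call. = FALSE)
      character(0)
    }))
  }
  invisible(paths)
}
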