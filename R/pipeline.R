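#' Run the full chemical-space-mapping pipeline
#'
#' Executes the preprocessing chain described by a [mapping_config] --
#' feature selection, dissimilarity computation, clustering, 3D embedding --
#' followed by the quality diagnostics (global embedding quality, per-compound
#' stress, duplicate-position detection) and optional annotation stages (SALI
#' activity-cliff aggregates, an applicability domain). Identical config +
#' dataset yield byte-identical outputs. Warnings that an interactive viewer
#' would raise (embedding quality below 0.6; n compounds on fewer than n
#' distinct positions; dataset/config hash mismatch) are collected in the run
#' log.
#'
#' @param dataset A [cs_dataset].
#' @param config A [mapping_config]. Supported names: distance `euclidean` /
#'   `tanimoto`; clustering `kmeans` / `hierarchical-average` /
#'   `hierarchical-ward` (parameter `k`, integer or `"auto"`); embedding
#'   `pca` / `sammon`.
#' @param output_dir If non-`NULL`, write `coordinates.csv` (one row per
#'   compound: index, name, x, y, z, cluster, endpoints, stress, optional
#'   annotations) and `run_log.txt` there.
#' @param compute_sali Add per-compound SALI aggregates (requires an endpoint;
#'   binary nominal endpoints are 0/1-encoded; similarity is Tanimoto for
#'   tanimoto mappings, else `1 - d/max(d)`).
#' @param ad_method Optional applicability domain: `"centroid"`, `"leverage"`
#'   or `"knn"` (on the standardized mapping features).
#' @param standardize Standardize numeric mapping features first (default
#'   `TRUE`; ignored for tanimoto/fragment features).
#' @return List of class `cs_mapping`: `coordinates` (annotated data.frame),
#'   `embedding`, `clustering`, `distances`, `quality`, `log` (character).
#' @export
run_pipeline <- function(dataset, config, output_dir = NULL,
                         compute_sali = FALSE, ad_method = NULL,
                         standardize = TRUE) {
  stopifnot(inherits(dataset, "cs_dataset"), inherits(config, "mapping_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }

  if (!is.na(config$dataset_hash)) {
    h <- dataset_hash(dataset)
    if (!identical(h, config$dataset_hash))
      note("WARNING: dataset content hash ", h,
           " does not match config hash ", config$dataset_hash)
  }
  features <- config$features
  if (length(features) == 0) features <- feature_names(dataset)
  note("features: ", paste(features, collapse = ", "))
  note("seed: ", config$seed)

  measure <- config$distance$name
  frag <- NULL
  if (measure == "tanimoto") {
    fm <- stage("featurize", {
      m <- as.matrix(dataset$features[features])
      storage.mode(m) <- "integer"
      fragment_matrix(m, features)
    })
    frag <- fm
    distances <- stage("distances", tanimoto_distances(fm))
    feat_input <- fm$matrix
  } else if (measure == "euclidean") {
    work <- if (standardize) stage("standardize", standardize_numeric(dataset, features))
            else dataset
    feat_input <- stage("featurize", feature_matrix(work, features))
    distances <- stage("distances", euclidean_distances(feat_input))
  } else stop("pipeline stage 'distances': unknown measure '", measure, "'",
              call. = FALSE)

  dup <- detect_duplicate_positions(feat_input, warn = FALSE)
  if (dup$n_distinct < n_compounds(dataset))
    note("WARNING: ", n_compounds(dataset), " compounds mapped to only ",
         dup$n_distinct, " distinct positions in 3D space due to identical ",
         "feature values")

  clu <- stage("clustering", {
    k <- config$clustering$k %||% "auto"
    if (config$clustering$name == "kmeans")
      cluster_compounds(feat_input, "kmeans", k = k, seed = config$seed,
                        distances = distances)
    else
      cluster_compounds(distances, config$clustering$name, k = k,
                        seed = config$seed)
  })
  note("clustering: ", clu$method, ", k = ", clu$k)

  emb <- stage("embedding", switch(
    config$embedding$name,
    pca = embed_pca(feat_input),
    sammon = embed_sammon(distances,
                          max_iter = config$embedding$max_iter %||% 500,
                          tol = config$embedding$tol %||% 1e-9,
                          seed = config$seed),
    stop("unknown embedding '", config$embedding$name, "'")
  ))
  if (identical(emb$algorithm, "sammon"))
    note("sammon stress: ", format(emb$stress, digits = 6))

  qual <- stage("quality", embedding_quality(distances, emb))
  note("embedding quality r = ", format(qual$r, digits = 4))
  if (qual$warning)
    note("WARNING: embedding quality below 0.6 -- moderate or weak embedding")

  coords <- data.frame(compound_index = dataset$compounds$index,
                       name = dataset$compounds$name,
                       emb$coords,
                       cluster = clu$labels)
  for (ep in dataset$endpoints) coords[[ep]] <- dataset$features[[ep]]
  if (!is.null(qual$stress)) coords$stress <- as.numeric(qual$stress)

  if (compute_sali) {
    sali <- stage("sali", {
      if (length(dataset$endpoints) == 0)
        stop("SALI requires an endpoint column")
      ep <- dataset$features[[dataset$endpoints[1]]]
      act <- if (is.numeric(ep)) ep else as.numeric(encode_binary(ep))
      sim <- if (measure == "tanimoto") 1 - distances$matrix
             else similarity_from_distances(distances)
      sali_features(sali_matrix(act, sim))
    })
    coords$sali_mean <- sali$mean
    coords$sali_sd <- sali$sd
    coords$sali_max <- sali$max
    coords$sali_n_infinite <- sali$n_infinite
  }
  if (!is.null(ad_method)) {
    ad <- stage("applicability", switch(
      ad_method,
      centroid = ad_centroid(feat_input),
      leverage = ad_leverage(feat_input),
      knn = ad_knn(feat_input),
      stop("unknown AD method '", ad_method, "'")
    ))
    coords$ad_score <- ad$score
    coords$ad_inside <- ad$inside
  }

  out <- structure(list(coordinates = coords, embedding = emb, clustering = clu,
                        distances = distances, quality = qual, fragments = frag,
                        config = config, log = log),
                   class = "cs_mapping")
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(format(coords, digits = 15, trim = TRUE),
                     file.path(output_dir, "coordinates.csv"), row.names = FALSE)
    writeLines(log, file.path(output_dir, "run_log.txt"))
  }
  out
}

#' @export
print.cs_mapping <- function(x, ...) {
  cat("<cs_mapping> ", nrow(x$coordinates), " compounds | ",
      x$embedding$algorithm, " embedding | ", x$clustering$k, " clusters | r = ",
      signif(x$quality$r, 4), "\n", sep = "")
  warns <- grep("^WARNING", x$log, value = TRUE)
  for (w in warns) cat("  ", w, "\n", sep = "")
  invisible(x)
}

#' Static 3D scatter export with dual-feature highlighting
#'
#' Replaces the interactive viewer's inner-sphere / outer-spheroid rendering
#' with a static orthographic 3D scatter: marker face colour encodes the
#' `inner` column (e.g. actual activity), marker edge colour the `outer`
#' column (e.g. aggregated prediction). Continuous columns are mapped over a
#' blue-to-red ramp (low values blue), optionally after a log transform for
#' skewed endpoints; nominal columns get a categorical palette. Deterministic
#' for identical inputs.
#'
#' @param coords Annotated coordinate `data.frame` (from [run_pipeline()]'s
#'   `coordinates`) with `x`, `y`, `z` columns.
#' @param inner Column name for the face colour.
#' @param outer Column name for the edge colour (defaults to `inner`).
#' @param path Output PNG path.
#' @param log_scale Apply `log10` to continuous colour columns (values must be
#'   positive).
#' @param width,height,pointsize Device parameters.
#' @return `path`, invisibly.
#' @export
export_plot <- function(coords, inner, outer = inner, path,
                        log_scale = FALSE, width = 900, height = 700,
                        pointsize = 14) {
  for (col in unique(c(inner, outer, "x", "y", "z")))
    if (!col %in% names(coords))
      stop("unknown column '", col, "'", call. = FALSE)

  colour_of <- function(vals) {
    if (is.numeric(vals)) {
      v <- vals
      if (log_scale) {
        if (any(v <= 0, na.rm = TRUE))
          stop("log scale requires positive values", call. = FALSE)
        v <- log10(v)
      }
      rng <- range(v, na.rm = TRUE)
      t <- if (diff(rng) == 0) rep(0.5, length(v)) else (v - rng[1]) / diff(rng)
      ramp <- grDevices::colorRamp(c("#2166AC", "#F7F7F7", "#B2182B"))
      grDevices::rgb(ramp(t), maxColorValue = 255)
    } else {
      lv <- sort(unique(as.character(vals)))
      pal <- grDevices::hcl.colors(max(3, length(lv)), "Dark 3")[seq_along(lv)]
      pal[match(as.character(vals), lv)]
    }
  }
  face <- colour_of(coords[[inner]])
  edge <- colour_of(coords[[outer]])

  # fixed isometric projection of the 3D coordinates
  px <- (coords$x - coords$y) * cos(pi / 6)
  py <- (coords$x + coords$y) * sin(pi / 6) + coords$z
  ord <- order(coords$x + coords$y, seq_along(px))  # back-to-front, stable

  grDevices::png(path, width = width, height = height, pointsize = pointsize)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(2, 2, 3, 8), xpd = NA)
  graphics::plot(px[ord], py[ord], pch = 21, bg = face[ord], col = edge[ord],
                 cex = 1.6, lwd = 2.2, axes = FALSE, xlab = "", ylab = "",
                 main = paste0("face: ", inner, "   edge: ", outer),
                 asp = 1)
  graphics::box()
  usr <- graphics::par("usr")
  graphics::legend(usr[2], usr[4],
                   legend = c(paste("face =", inner), paste("edge =", outer),
                              if (log_scale) "log10 colour scale"),
                   bty = "n", cex = 0.8)
  invisible(path)
}
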