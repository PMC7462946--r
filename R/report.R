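#' Mean map value inside a region
#'
#' Mean over the pixels of `roi` that lie on the vessel mask and carry a
#' defined map value; the contributing-pixel count is returned so
#' under-masked regions are visible.
#'
#' @param map a perfusion parameter map (matrix, `NA` = undefined).
#' @param roi an [roi_rect()] / [roi_circle()].
#' @param mask optional [vote_mask()] result restricting the mean to vessel
#'   pixels; `NULL` uses the whole region.
#' @return list with `value` (`NA` when no pixel contributes) and `n_pixels`.
#' @export
roi_mean <- function(map, roi, mask = NULL) {
  px <- roi_pixels(roi, dim(map))
  vals <- map[px]
  if (!is.null(mask)) vals <- vals[mask[px]]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) return(list(value = NA_real_, n_pixels = 0L))
  list(value = mean(vals), n_pixels = length(vals))
}

#' Percent rise of a post-treatment value over its baseline
#'
#' `100 * (post - pre) / pre`. Undefined (with a warning) when the baseline
#' is zero.
#'
#' @param pre baseline value (I0).
#' @param post post-treatment value (I).
#' @return percent rise; negative values are decreases.
#' @export
percent_rise <- function(pre, post) {
  out <- 100 * (post - pre) / pre
  zero <- !is.na(pre) & pre == 0
  if (any(zero)) {
    warning("percent rise undefined for zero baseline")
    out[zero] <- NA_real_
  }
  out
}

#' Pre/post comparison table over analysis ROIs
#'
#' For each metric (MTT, PBF, PBV) and each analysis region: the region mean
#' on the pre-therapy map with the region as drawn, the region mean on the
#' post-therapy map with the region transferred through the anchor, and the
#' percent rise. Rows are ordered metric-major.
#'
#' @param pre_maps,post_maps [compute_perfusion_maps()] results for the two
#'   series.
#' @param rois list of analysis ROIs drawn on the pre-therapy maps.
#' @param anchor an [anchor_pair()]; `NULL` means the series are already
#'   aligned (identity transfer).
#' @return data frame of class `pdsa_comparison` with columns `metric`,
#'   `artery_label`, `roi_id`, `pre_value`, `post_value`, `percent_rise`,
#'   `n_pixels_pre`, `n_pixels_post`.
#' @export
build_comparison <- function(pre_maps, post_maps, rois, anchor = NULL) {
  stopifnot(inherits(pre_maps, "perfusion_maps"),
            inherits(post_maps, "perfusion_maps"))
  if (inherits(rois, "roi")) rois <- list(rois)
  post_rois <- if (is.null(anchor)) rois
               else transfer_rois(rois, anchor, dim(post_maps$pbv))
  rows <- list()
  for (metric in c("MTT", "PBF", "PBV")) {
    key <- tolower(metric)
    for (i in seq_along(rois)) {
      pre <- roi_mean(pre_maps[[key]], rois[[i]], pre_maps$mask)
      post <- roi_mean(post_maps[[key]], post_rois[[i]], post_maps$mask)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric,
        artery_label = rois[[i]]$label,
        roi_id = rois[[i]]$id,
        pre_value = pre$value,
        post_value = post$value,
        percent_rise = percent_rise(pre$value, post$value),
        n_pixels_pre = pre$n_pixels,
        n_pixels_post = post$n_pixels,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pdsa_comparison", "data.frame")
  out
}

#' @export
print.pdsa_comparison <- function(x, ...) {
  cat("Pre/post perfusion comparison (", nrow(x), " rows)\n", sep = "")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Study-level summary of percent rises
#'
#' Counts, per metric, how many regions improved — an increase for
#' blood-flow and blood-volume metrics, a decrease for transit time (shorter
#' transit means better perfusion); a zero rise counts as not improved —
#' with the improved percentage (one decimal, half-up) and the arithmetic
#' mean rise. With patient assignments, each patient x metric is classified
#' `all decreased` / `all increased` / `mixed`.
#'
#' @param rows a [build_comparison()] result, or any data frame with columns
#'   `metric` and `percent_rise`.
#' @param patients optional vector (one element per row) of patient ids.
#' @return an object of class `pdsa_summary`: list with `metrics` (data
#'   frame: `metric`, `improved`, `total`, `pct_improved`, `mean_rise`) and
#'   `patients` (data frame of per-patient classifications, or `NULL`).
#' @export
summarize_comparison <- function(rows, patients = NULL) {
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0L) stop("no comparison rows to summarize")
  if (!is.null(patients) && length(patients) != nrow(rows))
    stop("'patients' must assign one patient per row")
  metrics <- unique(rows$metric)
  met <- do.call(rbind, lapply(metrics, function(m) {
    r <- rows$percent_rise[rows$metric == m]
    r <- r[!is.na(r)]
    improved <- if (m == "MTT") sum(r < 0) else sum(r > 0)
    data.frame(metric = m, improved = improved, total = length(r),
               pct_improved = round_half_up(100 * improved / length(r), 1L),
               mean_rise = mean(r), stringsAsFactors = FALSE)
  }))
  pat <- NULL
  if (!is.null(patients)) {
    combos <- unique(data.frame(patient = patients, metric = rows$metric,
                                stringsAsFactors = FALSE))
    combos$classification <- mapply(function(p, m) {
      r <- rows$percent_rise[patients == p & rows$metric == m]
      r <- r[!is.na(r)]
      if (all(r < 0)) "all decreased"
      else if (all(r > 0)) "all increased"
      else "mixed"
    }, combos$patient, combos$metric)
    pat <- combos[order(combos$metric, combos$patient), ]
    rownames(pat) <- NULL
  }
  structure(list(metrics = met, patients = pat), class = "pdsa_summary")
}

round_half_up <- function(x, digits = 0L) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' @export
print.pdsa_summary <- function(x, ...) {
  cat("Study summary\n")
  for (i in seq_len(nrow(x$metrics))) {
    r <- x$metrics[i, ]
    cat(sprintf("  %s: improved in %d/%d ROIs (%.1f%%), mean rise %.1f%%\n",
                r$metric, r$improved, r$total, r$pct_improved, r$mean_rise))
  }
  if (!is.null(x$patients)) {
    cat("  Per-patient classification:\n")
    for (i in seq_len(nrow(x$patients)))
      cat(sprintf("    patient %s, %s: %s\n", x$patients$patient[i],
                  x$patients$metric[i], x$patients$classification[i]))
  }
  invisible(x)
}

#' Write a study summary as JSON
#'
#' @param summary a [summarize_comparison()] result.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  out <- list(metrics = summary$metrics)
  if (!is.null(summary$patients)) out$patients <- summary$patients
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
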