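## Tissue masking by the scaled-MAD outlier rule, ROI summaries, radial
## line profiles, and the non-parametric statistical battery (Spearman,
## Kruskal-Wallis, pairwise rank-sum, Shapiro-Wilk gate).

#' Scaled-MAD outlier mask of a parameter map
#'
#' A pixel is an outlier iff `|x - median| > k * c * MAD` with
#' `c = 1.4826` (the consistency constant making the scaled MAD estimate a
#' normal standard deviation) and `k = 3` by default. The returned mask is
#' `TRUE` for retained (non-outlier, finite) pixels. An all-constant map has
#' no outliers.
#'
#' @param map numeric matrix (typically the total depolarization map).
#' @param k threshold multiplier (default 3).
#' @param scale_constant MAD scale constant (default 1.4826).
#' @return logical matrix, `TRUE` = retained.
#' @export
madMask <- function(map, k = 3, scale_constant = 1.4826) {
  fin <- is.finite(map)
  if (sum(fin) < 2) stop("map must have at least 2 finite values")
  x <- map[fin]
  med <- stats::median(x)
  m <- stats::mad(x, constant = scale_constant)
  keep <- fin
  if (m > 0) keep <- fin & (abs(map - med) <= k * m)
  keep[!fin] <- FALSE
  keep
}

#' Masked ROI summary of polarimetric maps
#'
#' Mean and maximum of each parameter map over a mask (one ROI acquisition =
#' one row of a sample table). The mask is computed with [madMask()] on a
#' configurable depolarization map if not supplied.
#'
#' @param maps a [PolarimetricMaps-class].
#' @param mask logical matrix, or `NULL` to derive one from `mask_on`.
#' @param mask_on map used for masking when `mask = NULL` (default
#'   `"Delta"`, total depolarization; `"DeltaL"`/`"DeltaC"` also sensible).
#' @param sample_id,batch_id,day,group design annotations carried into the
#'   row.
#' @return one-row `data.frame`: design columns, `n_pixels`, then
#'   `mean_<map>` and `max_<map>` for every map.
#' @export
roiSummary <- function(maps, mask = NULL, mask_on = "Delta",
                       sample_id = NA_character_, batch_id = NA_character_,
                       day = NA_integer_, group = NA_character_) {
  stopifnot(is(maps, "PolarimetricMaps"))
  if (is.null(mask)) mask <- madMask(paramMap(maps, mask_on))
  if (!any(mask)) stop("empty mask")
  row <- data.frame(sample_id = sample_id, batch_id = batch_id,
                    day = day, group = group, n_pixels = sum(mask),
                    stringsAsFactors = FALSE)
  for (nm in names(paramMaps(maps))) {
    v <- paramMap(maps, nm)[mask]
    v <- v[is.finite(v)]
    row[[paste0("mean_", nm)]] <- if (length(v)) mean(v) else NA_real_
    row[[paste0("max_", nm)]] <- if (length(v)) max(v) else NA_real_
  }
  row
}

#' Radial line profile of a parameter map across the ring
#'
#' Bins pixels of an annular sector by radial distance from the inner ring
#' edge and averages the map per bin. Returns the per-bin means, the
#' profile's standard deviation (spatial-heterogeneity statistic) and the
#' peak location.
#'
#' @param map numeric matrix.
#' @param center ring centre, `c(row, col)` in pixels.
#' @param innerRadius_um,width_um ring geometry in micrometres.
#' @param pitch_um pixel pitch in micrometres.
#' @param sector angular sector `c(from_deg, to_deg)` (default full ring).
#' @param n_bins number of radial bins.
#' @param mask optional logical matrix of pixels to include.
#' @return list with `profile` (data.frame: distance_um, value, n_pixels),
#'   `sd` (standard deviation of the binned profile), `peak_um` (argmax
#'   distance), `peak_value`.
#' @export
radialProfile <- function(map, center, innerRadius_um, width_um, pitch_um,
                          sector = c(0, 360), n_bins = 20, mask = NULL) {
  d <- dim(map)
  rr <- (row(map) - center[1]) * pitch_um
  cc <- (col(map) - center[2]) * pitch_um
  r <- sqrt(rr^2 + cc^2)
  if (innerRadius_um + width_um > max(r))
    stop("ring geometry extends beyond the image")
  ang <- (rad2deg(atan2(cc, rr)) + 360) %% 360
  inSector <- if (diff(sector) >= 360) rep(TRUE, length(ang)) else {
    a0 <- sector[1] %% 360; a1 <- sector[2] %% 360
    if (a0 <= a1) ang >= a0 & ang <= a1 else ang >= a0 | ang <= a1
  }
  dist_um <- r - innerRadius_um
  sel <- dist_um >= 0 & dist_um <= width_um & inSector & is.finite(map)
  if (!is.null(mask)) sel <- sel & mask
  edges <- seq(0, width_um, length.out = n_bins + 1)
  bin <- cut(dist_um[sel], edges, include.lowest = TRUE, labels = FALSE)
  vals <- map[sel]
  prof <- data.frame(
    distance_um = (edges[-1] + edges[-(n_bins + 1)]) / 2,
    value = vapply(seq_len(n_bins),
                   function(b) if (any(bin == b)) mean(vals[bin == b])
                               else NA_real_, numeric(1)),
    n_pixels = vapply(seq_len(n_bins),
                      function(b) sum(bin == b), numeric(1)))
  ok <- is.finite(prof$value)
  pk <- if (any(ok)) which.max(replace(prof$value, !ok, -Inf)) else NA
  list(profile = prof,
       sd = stats::sd(prof$value[ok]),
       peak_um = if (is.na(pk[1])) NA_real_ else prof$distance_um[pk],
       peak_value = if (is.na(pk[1])) NA_real_ else prof$value[pk])
}

#' Least-squares circle fit of ring geometry from a mask
#'
#' Plumbing for when the ring centre is not known a priori: algebraic
#' (Kasa) least-squares circle through the mask pixel coordinates.
#'
#' @param mask logical matrix of ring pixels.
#' @return list with `center` (row, col) and `radius_px` (mean radius of the
#'   mask pixels around the fitted centre).
#' @export
fitRingCenter <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 3) stop("mask too small to fit a circle")
  x <- idx[, 1]; y <- idx[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- qr.solve(A, b)
  ctr <- sol[1:2]
  list(center = unname(ctr),
       radius_px = mean(sqrt((x - ctr[1])^2 + (y - ctr[2])^2)))
}

#' Spearman correlation battery over a sample table
#'
#' Rank correlations among the per-ROI parameter means, and of each
#' parameter against the design variables day (ordinal) and group (binary).
#' Constant columns yield `NA` with a note. Two-sided p-values throughout.
#'
#' @param table a sample table (rows = ROI acquisitions) with `day`,
#'   `group` and `mean_*` columns.
#' @param params which parameter columns to use (default every `mean_*`).
#' @return list with `rho` and `p` (parameter-by-parameter matrices) and
#'   `design` (data.frame: parameter, rho_day, p_day, rho_group, p_group).
#' @export
spearmanBattery <- function(table, params = NULL) {
  if (nrow(table) < 3) stop("need at least 3 rows")
  if (is.null(params)) params <- grep("^mean_", names(table), value = TRUE)
  X <- as.matrix(table[, params, drop = FALSE])
  k <- length(params)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(params, params))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    xi <- X[, i]; xj <- X[, j]
    if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next
    ct <- suppressWarnings(
      stats::cor.test(xi, xj, method = "spearman", exact = FALSE))
    rho[i, j] <- unname(ct$estimate); p[i, j] <- ct$p.value
  }
  groupNum <- as.integer(factor(table$group))
  design <- do.call(rbind, lapply(params, function(nm) {
    x <- table[[nm]]
    sp_d <- if (stats::sd(x) > 0) suppressWarnings(
      stats::cor.test(x, table$day, method = "spearman", exact = FALSE))
      else NULL
    sp_g <- if (stats::sd(x) > 0 && length(unique(groupNum)) > 1)
      suppressWarnings(
        stats::cor.test(x, groupNum, method = "spearman", exact = FALSE))
      else NULL
    data.frame(parameter = nm,
               rho_day = if (is.null(sp_d)) NA else unname(sp_d$estimate),
               p_day = if (is.null(sp_d)) NA else sp_d$p.value,
               rho_group = if (is.null(sp_g)) NA else unname(sp_g$estimate),
               p_group = if (is.null(sp_g)) NA else sp_g$p.value)
  }))
  list(rho = rho, p = p, design = design)
}

#' Non-parametric group-comparison battery
#'
#' Per group (arm): Kruskal-Wallis across days, then unadjusted pairwise
#' two-sample Wilcoxon rank-sum tests between all day pairs (original
#' p-values; Holm adjustment available behind `adjust`). Per day: rank-sum
#' test between the two groups. Optionally a Shapiro-Wilk normality report
#' per (day, group) cell. Rank-sum tests are exact for small samples without
#' ties; midranks with normal approximation and continuity correction
#' otherwise (the `stats::wilcox.test` behaviour).
#'
#' @param table sample table with `day`, `group` and the response column.
#' @param param response column name (e.g. `"mean_delta_deg"`).
#' @param adjust p-adjustment method for the pairwise tests (default
#'   `"none"`, mirroring an unadjusted post-hoc battery; e.g. `"holm"`).
#' @param shapiro include a per-cell Shapiro-Wilk normality report.
#' @return list with `kruskal` (per group), `pairwise_days` (per group, all
#'   day pairs), `between_groups` (per day), and optionally `shapiro`.
#' @export
groupTests <- function(table, param, adjust = "none", shapiro = TRUE) {
  stopifnot(param %in% names(table))
  x <- table[[param]]
  groups <- unique(table$group)
  kr <- do.call(rbind, lapply(groups, function(g) {
    sel <- table$group == g
    if (length(unique(table$day[sel])) < 2) return(NULL)
    kt <- stats::kruskal.test(x[sel], factor(table$day[sel]))
    data.frame(group = g, statistic = unname(kt$statistic),
               df = unname(kt$parameter), p = kt$p.value)
  }))
  pw <- do.call(rbind, lapply(groups, function(g) {
    sel <- table$group == g
    days <- sort(unique(table$day[sel]))
    if (length(days) < 2) return(NULL)
    cmb <- utils::combn(days, 2)
    out <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
      d1 <- cmb[1, k]; d2 <- cmb[2, k]
      a <- x[sel & table$day == d1]; b <- x[sel & table$day == d2]
      if (length(a) < 2 || length(b) < 2) return(NULL)
      wt <- suppressWarnings(stats::wilcox.test(a, b))
      data.frame(group = g, day1 = d1, day2 = d2, n1 = length(a),
                 n2 = length(b), W = unname(wt$statistic), p = wt$p.value)
    }))
    if (!is.null(out)) out$p_adj <- stats::p.adjust(out$p, method = adjust)
    out
  }))
  bg <- NULL
  if (length(groups) == 2) {
    bg <- do.call(rbind, lapply(sort(unique(table$day)), function(d) {
      a <- x[table$day == d & table$group == groups[1]]
      b <- x[table$day == d & table$group == groups[2]]
      if (length(a) < 2 || length(b) < 2) return(NULL)
      wt <- suppressWarnings(stats::wilcox.test(a, b))
      data.frame(day = d, n1 = length(a), n2 = length(b),
                 W = unname(wt$statistic), p = wt$p.value)
    }))
  }
  out <- list(kruskal = kr, pairwise_days = pw, between_groups = bg)
  if (shapiro) {
    out$shapiro <- do.call(rbind, lapply(groups, function(g) {
      do.call(rbind, lapply(sort(unique(table$day)), function(d) {
        v <- x[table$group == g & table$day == d]
        if (length(v) < 3 || stats::sd(v) == 0) return(NULL)
        st <- stats::shapiro.test(v)
        data.frame(group = g, day = d, n = length(v),
                   W = unname(st$statistic), p = st$p.value)
      }))
    }))
  }
  out
}
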