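#' Fit a GGE model to a cell-mean table
#'
#' The table is environment-centered (each test site's mean subtracted;
#' no transformation, no scaling), leaving genotype main effects plus
#' genotype-by-environment interaction (G + GE), and decomposed by SVD,
#' \deqn{\bar Y_{ij} - \bar Y_{.j} = \sum_k \lambda_k \gamma_{ik} \delta_{jk}.}
#' Singular values are allocated to the displayed scores by the singular
#' value partitioning (SVP) mode: `"environment"`-focused gives
#' \eqn{(\gamma, \lambda\delta)} (appropriate for comparing environments,
#' the default), `"genotype"`-focused \eqn{(\lambda\gamma, \delta)}, and
#' `"symmetric"` \eqn{(\lambda^{1/2}\gamma, \lambda^{1/2}\delta)}. The same
#' deterministic sign convention as [fit_ammi()] is applied.
#'
#' @param table A `two_way_table` from [cell_means()], or a numeric matrix.
#' @param svp_mode `"environment"`, `"genotype"` or `"symmetric"`.
#'
#' @return A `gge_fit` with `centered` (the environment-centered matrix),
#'   `singular_values`, `genotype_scores`, `environment_scores` (all
#'   components, SVP-scaled), `svp_mode`, `explained` (percent of total
#'   G+GE per component) and `residual` (beyond the first two components).
#' @export
#' @examples
#' sim <- simulate_met(sim_config(n_genotypes = 30, n_environments = 5,
#'                                blocks_per_rep = 5, seed = 11))
#' fit <- fit_gge(cell_means(sim$records, "yield"))
#' fit$explained[1:2]
fit_gge <- function(table, svp_mode = c("environment", "genotype",
                                        "symmetric")) {
  svp_mode <- match.arg(svp_mode)
  m <- if (inherits(table, "two_way_table")) table$values else as.matrix(table)
  if (anyNA(m)) stop("incomplete table", call. = FALSE)
  g <- nrow(m); e <- ncol(m)
  if (g < 2 || e < 2) stop("need >= 2 genotypes and >= 2 environments",
                           call. = FALSE)
  centered <- sweep(m, 2, colMeans(m))
  kmax <- min(g, e)
  sv <- svd(centered, nu = kmax, nv = kmax)
  lambda <- sv$d[seq_len(kmax)]
  gamma <- sv$u
  delta <- sv$v
  for (k in seq_len(kmax)) {
    if (delta[which.max(abs(delta[, k])), k] < 0) {
      gamma[, k] <- -gamma[, k]
      delta[, k] <- -delta[, k]
    }
  }
  # null components: the SVD basis beyond the rank is arbitrary, so their
  # scores are identically zero rather than backend-dependent noise
  null_comp <- lambda <= 1e-12 * max(lambda[1], 0)
  gamma[, null_comp] <- 0
  delta[, null_comp] <- 0
  scl <- switch(svp_mode,
                environment = list(g = rep(1, kmax), e = lambda),
                genotype = list(g = lambda, e = rep(1, kmax)),
                symmetric = list(g = sqrt(lambda), e = sqrt(lambda)))
  gscore <- sweep(gamma, 2, scl$g, `*`)
  escore <- sweep(delta, 2, scl$e, `*`)
  rownames(gscore) <- rownames(m); rownames(escore) <- colnames(m)
  rank2 <- gamma[, 1:2, drop = FALSE] %*%
    (lambda[1:2] * t(delta[, 1:2, drop = FALSE]))
  total <- sum(lambda^2)
  structure(
    list(centered = centered, singular_values = lambda,
         genotype_scores = gscore, environment_scores = escore,
         svp_mode = svp_mode,
         explained = if (total > 0) 100 * lambda^2 / total
                     else rep(0, kmax),
         residual = centered - rank2),
    class = "gge_fit"
  )
}

#' @export
print.gge_fit <- function(x, ...) {
  cat("GGE fit (", x$svp_mode, "-focused SVP): ",
      nrow(x$genotype_scores), " genotypes x ",
      nrow(x$environment_scores), " environments\n", sep = "")
  cat("PC1 + PC2 explain ", sprintf("%.1f", sum(x$explained[1:2])),
      "% of G+GE\n", sep = "")
  invisible(x)
}

gge_scores2 <- function(fit, side) {
  sc <- if (side == "genotype") fit$genotype_scores else fit$environment_scores
  sc[, 1:2, drop = FALSE]
}

#' Which-won-where sector partition
#'
#' Builds the polygon (convex hull) of the genotype scores in the first two
#' components, drops a boundary ray from the origin perpendicular to each
#' hull side, and assigns each environment to the angular sector its score
#' vector falls in. The hull vertex inside a sector is the winning genotype
#' for every environment in that sector. Environments on a boundary ray go
#' to the counter-clockwise sector; environments with a zero score vector
#' are left unassigned.
#'
#' @param fit A [fit_gge()] result with at least 3 non-collinear genotypes.
#' @return A `gge_sectors` list with `hull_vertices` (genotypes,
#'   counter-clockwise), `boundaries` (tibble of ray angles in radians),
#'   `environments` (tibble: environment, angle, sector, winner) and
#'   `winners` (tibble: sector, genotype).
#' @export
which_won_where <- function(fit) {
  gs <- gge_scores2(fit, "genotype")
  es <- gge_scores2(fit, "environment")
  hull <- grDevices::chull(gs[, 1], gs[, 2])    # clockwise order
  if (length(hull) < 3) {
    stop("genotype scores are collinear; polygon view undefined",
         call. = FALSE)
  }
  hull <- rev(hull)                             # counter-clockwise
  nv <- length(hull)

  # Ray perpendicular to the edge (v, next v), oriented away from the hull
  # interior (the origin is inside the hull since genotype scores average 0).
  edge_ray <- function(i) {
    a <- gs[hull[i], ]; b <- gs[hull[i %% nv + 1], ]
    d <- b - a
    ray <- c(d[2], -d[1])                       # outward normal for ccw hull
    atan2(ray[2], ray[1])
  }
  ray_angle <- vapply(seq_len(nv), edge_ray, numeric(1))

  # Sector of vertex i lies between the rays of its incident edges
  # (previous edge's ray, this edge's ray), counter-clockwise.
  env_angle <- atan2(es[, 2], es[, 1])
  env_len <- sqrt(rowSums(es^2))

  ccw_between <- function(theta, from, to) {
    # theta in [from, to) counter-clockwise: a vector on a boundary ray
    # belongs to the sector counter-clockwise of the ray.
    span <- (to - from) %% (2 * pi)
    off <- (theta - from) %% (2 * pi)
    off < span - 1e-12 || off < 1e-12 || off > 2 * pi - 1e-12
  }
  sector_of <- function(theta) {
    for (i in seq_len(nv)) {
      from <- ray_angle[if (i == 1) nv else i - 1]
      to <- ray_angle[i]
      if (ccw_between(theta, from, to)) return(i)
    }
    NA_integer_
  }
  sector <- ifelse(env_len < 1e-12, NA_integer_,
                   vapply(env_angle, sector_of, integer(1)))
  hull_names <- rownames(gs)[hull]
  environments <- tibble::tibble(
    environment = rownames(es),
    angle = env_angle,
    sector = as.integer(sector),
    winner = ifelse(is.na(sector), NA_character_, hull_names[sector])
  )
  structure(
    list(hull_vertices = hull_names,
         boundaries = tibble::tibble(sector = seq_len(nv),
                                     angle = ray_angle),
         environments = environments,
         winners = tibble::tibble(sector = seq_len(nv),
                                  genotype = hull_names)),
    class = "gge_sectors"
  )
}

#' @export
print.gge_sectors <- function(x, ...) {
  cat("Which-won-where: ", length(x$hull_vertices), " polygon vertices (",
      paste(x$hull_vertices, collapse = ", "), ")\n", sep = "")
  occupied <- stats::na.omit(unique(x$environments$sector))
  cat(length(occupied), " environment-group(s)\n", sep = "")
  print(x$environments)
  invisible(x)
}

# Average environment axis: unit vector along the mean environment score.
aea_direction <- function(fit) {
  es <- gge_scores2(fit, "environment")
  avg <- colMeans(es)
  len <- sqrt(sum(avg^2))
  if (len < 1e-12) {
    stop("average environment vector has zero length; AEA undefined",
         call. = FALSE)
  }
  avg / len
}

#' Mean performance vs stability along the average environment axis
#'
#' Projects each genotype's 2-D score onto the average environment axis
#' (AEA, the direction of the mean environment vector). The on-axis
#' projection orders genotypes by mean performance; the signed perpendicular
#' component measures instability (larger magnitude = more interaction).
#'
#' @param fit A [fit_gge()] result.
#' @return A tibble with `genotype`, `mean_projection`,
#'   `stability_projection`, carrying the unit AEA as attribute `"aea"`.
#' @export
mean_vs_stability <- function(fit) {
  aea <- aea_direction(fit)
  perp <- c(-aea[2], aea[1])
  gs <- gge_scores2(fit, "genotype")
  out <- tibble::tibble(
    genotype = rownames(gs),
    mean_projection = as.vector(gs %*% aea),
    stability_projection = as.vector(gs %*% perp)
  )
  attr(out, "aea") <- aea
  out
}

#' Discriminativeness and representativeness of environments
#'
#' An environment's vector length (norm of its 2-D score) measures its power
#' to discriminate genotypes; the cosine of its angle with the average
#' environment axis measures how representative it is of the average
#' environment. A zero-length vector has undefined cosine, reported as `NA`.
#'
#' @param fit A [fit_gge()] result.
#' @return A tibble with `environment`, `vector_length`, `cos_aea`.
#' @export
discriminativeness_representativeness <- function(fit) {
  aea <- aea_direction(fit)
  es <- gge_scores2(fit, "environment")
  len <- unname(sqrt(rowSums(es^2)))
  tibble::tibble(
    environment = rownames(es),
    vector_length = len,
    cos_aea = ifelse(len < 1e-12, NA_real_, as.vector(es %*% aea) / len)
  )
}

#' Distance to the ideal genotype
#'
#' The ideal genotype sits on the average environment axis at the largest
#' observed mean projection (highest mean performance, zero instability).
#' Genotypes are ranked by Euclidean distance to that point: the closest is
#' the most desirable, combining performance and stability.
#'
#' @param fit A [fit_gge()] result.
#' @return A tibble with `genotype`, `distance`, `rank` (fractional on
#'   ties), sorted ascending by distance.
#' @export
ideal_genotype_distance <- function(fit) {
  aea <- aea_direction(fit)
  ms <- mean_vs_stability(fit)
  ideal <- aea * max(ms$mean_projection)
  gs <- gge_scores2(fit, "genotype")
  d <- sqrt((gs[, 1] - ideal[1])^2 + (gs[, 2] - ideal[2])^2)
  out <- tibble::tibble(
    genotype = rownames(gs),
    distance = unname(d),
    rank = rank_with_ties(unname(d), ascending = TRUE)
  )
  dplyr::arrange(out, .data$distance)
}

#' @rdname tidy.gge_fit
#' @method glance gge_fit
#' @export
glance.gge_fit <- function(x, ...) {
  tibble::tibble(
    n_genotypes = nrow(x$genotype_scores),
    n_environments = nrow(x$environment_scores),
    svp_mode = x$svp_mode,
    explained_pc1 = x$explained[1],
    explained_pc2 = x$explained[2],
    explained_pc1_pc2 = sum(x$explained[1:2])
  )
}

#' Tidy a GGE fit
#'
#' @param x A `gge_fit`.
#' @param ... Unused.
#' @return A tibble of genotype and environment 2-D scores with the percent
#'   of G+GE each axis explains attached as attribute `"explained"`.
#' @method tidy gge_fit
#' @export
tidy.gge_fit <- function(x, ...) {
  gs <- gge_scores2(x, "genotype"); es <- gge_scores2(x, "environment")
  out <- tibble::tibble(
    type = rep(c("genotype", "environment"), c(nrow(gs), nrow(es))),
    id = c(rownames(gs), rownames(es)),
    pc1 = unname(c(gs[, 1], es[, 1])),
    pc2 = unname(c(gs[, 2], es[, 2]))
  )
  attr(out, "explained") <- x$explained[1:2]
  out
}

#' GGE biplot
#'
#' @param object A `gge_fit`.
#' @param type `"biplot"` (scores with environment vectors),
#'   `"which_won_where"` (polygon and sector boundaries) or
#'   `"mean_vs_stability"` (AEA axis and projections).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gge_fit
#' @export
autoplot.gge_fit <- function(object, type = c("biplot", "which_won_where",
                                              "mean_vs_stability"), ...) {
  type <- match.arg(type)
  sc <- tidy(object)
  gen <- dplyr::filter(sc, .data$type == "genotype")
  env <- dplyr::filter(sc, .data$type == "environment")
  expl <- attr(sc, "explained")
  p <- ggplot2::ggplot(mapping = ggplot2::aes(x = .data$pc1, y = .data$pc2)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(data = gen, alpha = 0.5, size = 1) +
    ggplot2::geom_segment(data = env,
                          ggplot2::aes(x = 0, y = 0, xend = .data$pc1,
                                       yend = .data$pc2),
                          colour = "steelblue",
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_text(data = env, ggplot2::aes(label = .data$id),
                       colour = "steelblue", vjust = -0.5) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", expl[1]),
                  y = sprintf("PC2 (%.1f%%)", expl[2])) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
  if (type == "which_won_where") {
    ww <- which_won_where(object)
    hull <- gen[match(c(ww$hull_vertices, ww$hull_vertices[1]), gen$id), ]
    rmax <- max(sqrt(sc$pc1^2 + sc$pc2^2))
    rays <- dplyr::mutate(ww$boundaries,
                          xend = rmax * cos(.data$angle),
                          yend = rmax * sin(.data$angle))
    p <- p +
      ggplot2::geom_path(data = hull, colour = "grey30") +
      ggplot2::geom_segment(data = rays,
                            ggplot2::aes(x = 0, y = 0, xend = .data$xend,
                                         yend = .data$yend),
                            linetype = 3, colour = "grey30") +
      ggplot2::geom_text(data = gen[gen$id %in% ww$hull_vertices, ],
                         ggplot2::aes(label = .data$id), vjust = 1.5)
  }
  if (type == "mean_vs_stability") {
    aea <- attr(mean_vs_stability(object), "aea")
    rmax <- max(sqrt(sc$pc1^2 + sc$pc2^2))
    p <- p + ggplot2::annotate("segment", x = -rmax * aea[1],
                               y = -rmax * aea[2], xend = rmax * aea[1],
                               yend = rmax * aea[2], colour = "firebrick",
                               arrow = ggplot2::arrow(length = ggplot2::unit(3, "mm")))
  }
  p
}
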