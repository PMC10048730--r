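#' Build a saturated gravity-model network
#'
#' Constructs the full directed dyad list (all ordered pairs of
#' individuals) for a singly-constrained gravity model of gene flow. Edge
#' covariates: Euclidean distance between the members' coordinates (omega)
#' and any number of between-site resistance distances (c). Node
#' covariates (upsilon): site-level attributes (e.g. IVI, NDVI, canopy
#' height, basal area, stem density, ENS, topographic SD), attached to each
#' dyad from its destination individual's site — every individual sampled
#' at a site carries the same within-site conditions.
#'
#' @param nodes a [genotype_table()] with locality and coordinates, or a
#'   data frame with columns `id`, `site`, `x`, `y`.
#' @param site_attrs data frame with a `site` column plus attribute
#'   columns; every site present among the nodes must appear.
#' @param response a [pairwise_matrix()] of Dps gene-flow values.
#' @param resistances named list of [pairwise_matrix()] resistance / commute
#'   distances (optional).
#' @return A `gravity_network` data frame: `from`, `to`, `from_site`,
#'   `to_site`, `distance`, one column per resistance, one per site
#'   attribute, and `dps`.
#' @export
build_gravity_network <- function(nodes, site_attrs, response,
                                  resistances = list()) {
  if (inherits(nodes, "genotype_table")) {
    if (is.null(nodes$coords)) stop("genotype table has no coordinates")
    nd <- data.frame(id = nodes$ids, site = nodes$locality,
                     x = nodes$coords[, 1], y = nodes$coords[, 2],
                     stringsAsFactors = FALSE)
  } else {
    nd <- as.data.frame(nodes)
    if (!all(c("id", "site", "x", "y") %in% names(nd)))
      stop("nodes need columns id, site, x, y")
    nd$id <- as.character(nd$id)
  }
  sa <- as.data.frame(site_attrs)
  if (!"site" %in% names(sa)) names(sa)[1] <- "site"
  sa$site <- as.character(sa$site)
  missing_sites <- setdiff(unique(nd$site), sa$site)
  if (length(missing_sites))
    stop("no attributes for site(s): ", paste(missing_sites, collapse = ", "))
  attr_cols <- setdiff(names(sa), "site")

  n <- nrow(nd)
  pairs <- expand.grid(to = seq_len(n), from = seq_len(n))[, c("from", "to")]
  pairs <- pairs[pairs$from != pairs$to, ]
  net <- data.frame(
    from = nd$id[pairs$from],
    to = nd$id[pairs$to],
    from_site = nd$site[pairs$from],
    to_site = nd$site[pairs$to],
    distance = sqrt((nd$x[pairs$from] - nd$x[pairs$to])^2 +
                      (nd$y[pairs$from] - nd$y[pairs$to])^2),
    stringsAsFactors = FALSE)
  for (rn in names(resistances)) {
    rmat <- pm_restrict(resistances[[rn]], nd$id)
    net[[rn]] <- rmat[cbind(pairs$from, pairs$to)]
  }
  dmat <- pm_restrict(response, nd$id)
  net$dps <- dmat[cbind(pairs$from, pairs$to)]
  dest_attr <- sa[match(net$to_site, sa$site), attr_cols, drop = FALSE]
  rownames(dest_attr) <- NULL
  net <- cbind(net, dest_attr)
  structure(net, class = c("gravity_network", "data.frame"),
            attr_cols = attr_cols, resistance_cols = names(resistances))
}

#' Gravity-model AIC convention
#'
#' `AIC = 2 k_eff - 2 logL` with `k_eff` the number of fixed effects
#' (intercept, distance, extra covariates) plus the two variance components
#' (origin-node intercept, residual).
#'
#' @param logL (restricted) maximum log-likelihood.
#' @param k_eff effective parameter count.
#' @export
gravity_aic <- function(logL, k_eff) 2 * k_eff - 2 * logL

#' Fit a singly-constrained gravity model
#'
#' Log-log mixed model of gene flow on a saturated dyad network: the
#' response `log(Dps)` is regressed on `log(distance)` and log-transformed
#' covariates, with a random intercept per origin node — the single
#' constraint of the gravity formulation. Fit by REML (the reporting
#' convention; `ml = TRUE` refits by ML for nested comparisons) via
#' `lmerTest::lmer`, with Satterthwaite degrees of freedom.
#'
#' Zero responses are raised by a configurable offset (default half the
#' smallest positive value) and covariates with non-positive values are
#' shifted positive; both adjustments are reported with a message.
#'
#' @param net a [build_gravity_network()] result.
#' @param covariates character vector of covariate columns (site attributes
#'   and/or resistance distances); empty for the pure
#'   isolation-by-distance model.
#' @param include_distance include `log(distance)` (default `TRUE`).
#' @param constraint `"origin"` (default) or `"destination"` random
#'   intercept.
#' @param ml fit by ML instead of REML.
#' @param zero_offset offset added to zero responses; default half the
#'   minimum positive response.
#' @return A `gravity_fit`: `coefficients` table (beta, se, df, t, p),
#'   `logL`, `k_eff`, `aic`, and the underlying `model`.
#' @export
fit_gravity <- function(net, covariates = character(),
                        include_distance = TRUE,
                        constraint = c("origin", "destination"),
                        ml = FALSE, zero_offset = NULL) {
  constraint <- match.arg(constraint)
  if (!inherits(net, "gravity_network")) stop("net must be a gravity_network")
  miss <- setdiff(covariates, names(net))
  if (length(miss)) stop("unknown covariates: ", paste(miss, collapse = ", "))
  d <- as.data.frame(net)

  y <- d$dps
  if (any(!is.finite(y)) || any(y < 0))
    stop("response must be finite and non-negative")
  if (any(y == 0)) {
    off <- if (is.null(zero_offset)) min(y[y > 0]) / 2 else zero_offset
    message(sprintf("raising %d zero responses by offset %g",
                    sum(y == 0), off))
    y[y == 0] <- off
  }
  if (any(y > 1 + 1e-9)) stop("Dps response must lie in (0, 1]")
  d$.ly <- log(y)

  logpos <- function(x, nm) {
    if (any(x <= 0)) {
      shift <- -min(x) + 0.001 * diff(range(x))
      if (!is.finite(shift) || shift <= 0) shift <- 1e-6
      message(sprintf("covariate '%s' has non-positive values; shifting by %g before log",
                      nm, shift))
      x <- x + shift
    }
    log(x)
  }
  terms <- character(0)
  if (include_distance) {
    d$.ldist <- logpos(d$distance, "distance")
    terms <- ".ldist"
  }
  for (cv in covariates) {
    col <- paste0(".l_", cv)
    d[[col]] <- logpos(d[[cv]], cv)
    terms <- c(terms, col)
  }
  if (!length(terms)) stop("model has no covariates")
  grp <- if (constraint == "origin") "from" else "to"
  fml <- stats::as.formula(paste(".ly ~", paste(terms, collapse = " + "),
                                 "+ (1 |", grp, ")"))
  fit <- lmerTest::lmer(fml, data = d, REML = !ml)
  sm <- stats::coef(summary(fit))
  nice <- c("(Intercept)",
            if (include_distance) "distance",
            covariates)
  coefs <- data.frame(term = nice,
                      beta = sm[, "Estimate"],
                      se = sm[, "Std. Error"],
                      df = sm[, "df"],
                      t = sm[, "t value"],
                      p = sm[, "Pr(>|t|)"],
                      row.names = NULL)
  logL <- as.numeric(stats::logLik(fit))
  k_eff <- nrow(sm) + 2L
  structure(list(coefficients = coefs,
                 logL = logL, k_eff = k_eff,
                 k_printed = max(1L, length(covariates)),
                 aic = gravity_aic(logL, k_eff),
                 reml = !ml, constraint = constraint,
                 model = fit),
            class = "gravity_fit")
}

#' @export
print.gravity_fit <- function(x, ...) {
  cat(sprintf("<gravity_fit> %s, %s-constrained\n",
              if (x$reml) "REML" else "ML", x$constraint))
  cf <- x$coefficients
  cf[, -1] <- round(cf[, -1], 4)
  print(cf)
  cat(sprintf("  logL = %.4f, k_eff = %d, AIC = %.4f\n",
              x$logL, x$k_eff, x$aic))
  invisible(x)
}

#' Ranked gravity-model comparison table
#'
#' Fits each candidate covariate set and tabulates the printed covariate
#' count `K`, log-likelihood, and AIC, sorted by decreasing support
#' (log-likelihood). Include an empty covariate set as the
#' isolation-by-distance null.
#'
#' @param net a [build_gravity_network()] result.
#' @param formulas named list of covariate character vectors
#'   (`character(0)` = IBD null).
#' @param ml fit by ML (for strict nested comparisons) instead of REML.
#' @return A data frame `model, K, logL, AIC` sorted by support.
#' @export
gravity_model_table <- function(net, formulas, ml = FALSE) {
  if (length(formulas) < 2L)
    stop("need at least two candidate models (including the IBD null)")
  if (is.null(names(formulas)))
    stop("formulas must be named")
  rows <- lapply(names(formulas), function(nm) {
    f <- fit_gravity(net, covariates = formulas[[nm]], ml = ml)
    data.frame(model = nm, K = f$k_printed, logL = f$logL, AIC = f$aic)
  })
  out <- do.call(rbind, rows)
  out[order(-out$logL), ]
}
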