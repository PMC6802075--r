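#' Read a specimen-level trait table
#'
#' Expects a delimited file with header `species, specimen, trait, value`
#' (the `specimen` column may be absent, implying one specimen per species).
#' Values are on the natural-log scale unless `ln_transform = TRUE`.
#'
#' @param path Comma- or tab-separated file.
#' @param ln_transform Apply `log()` to `value` on input?
#' @return Tibble with columns `species`, `specimen`, `trait`, `value`.
#' @export
read_trait_table <- function(path, ln_transform = FALSE) {
  tab <- readr::read_delim(path, delim = guess_delim(path),
                           show_col_types = FALSE)
  if (!"specimen" %in% names(tab)) tab$specimen <- 1L
  need <- c("species", "specimen", "trait", "value")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("trait table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  tab <- tibble::as_tibble(tab[need])
  if (ln_transform) tab$value <- log(tab$value)
  if (anyNA(tab$value) || any(!is.finite(tab$value)))
    stop("non-finite trait value present", call. = FALSE)
  tab
}

#' Read a body-mass table
#'
#' Expects columns `species` and `mass_g` (grams) or `ln_mass`.
#'
#' @param path Comma- or tab-separated file.
#' @return Named numeric vector of ln body mass per species.
#' @export
read_mass_table <- function(path) {
  tab <- readr::read_delim(path, delim = guess_delim(path),
                           show_col_types = FALSE)
  if ("ln_mass" %in% names(tab)) m <- tab$ln_mass
  else if ("mass_g" %in% names(tab)) m <- log(tab$mass_g)
  else stop("mass table needs a 'mass_g' or 'ln_mass' column", call. = FALSE)
  setNames(m, tab$species)
}

guess_delim <- function(path) {
  l1 <- readLines(path, n = 1)
  if (grepl("\t", l1)) "\t" else ","
}

#' Regress a trait on body mass and return residuals
#'
#' Ordinary least-squares regression of ln(trait) on ln(body mass) over all
#' species with both values (species with several specimens are averaged
#' first).  No phylogenetic correction is applied.  The residuals come from
#' the plain OLS fit; the optional residual-randomization permutation test
#' (type-I sums of squares) affects only the reported p-value.
#'
#' @param traits Trait table (see [read_trait_table()]).
#' @param mass Named numeric vector of ln body mass per species.
#' @param trait Trait id to fit.
#' @param n_perm Permutation rounds for the significance test (0 = skip).
#' @param seed Seed for the permutation test.
#' @return An `allometry_fit`: list with `trait`, `intercept`, `slope`,
#'   `r_squared`, `p_value`, `residuals` (named by species), `n`,
#'   `excluded` (species lacking mass).
#' @export
fit_allometry <- function(traits, mass, trait, n_perm = 10000, seed = 1L) {
  tt <- traits[traits$trait == trait, ]
  if (!nrow(tt)) stop("no rows for trait '", trait, "'", call. = FALSE)
  means <- tapply(tt$value, tt$species, mean)
  sp <- names(means)
  excluded <- sp[!(sp %in% names(mass)) | !is.finite(mass[sp])]
  sp <- setdiff(sp, excluded)
  if (length(sp) < 3) stop("need >= 3 species with both trait and mass",
                           call. = FALSE)
  y <- as.numeric(means[sp])
  m <- as.numeric(mass[sp])
  if (var(m) == 0) stop("zero variance in ln body mass", call. = FALSE)
  fit <- stats::lm(y ~ m)
  res <- setNames(as.numeric(stats::residuals(fit)), sp)
  ss_tot <- sum((y - mean(y))^2)
  ss_reg <- ss_tot - sum(res^2)
  p_value <- NA_real_
  if (n_perm > 0) {
    # residual randomization under the intercept-only reduced model:
    # permute centred responses, recompute the regression sum of squares
    set.seed(seed)
    yc <- y - mean(y)
    mc <- m - mean(m)
    smm <- sum(mc^2)
    obs <- ss_reg
    perm <- replicate(n_perm, {
      yp <- sample(yc)
      sum(mc * yp)^2 / smm
    })
    p_value <- (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
  }
  structure(list(trait = trait, intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 r_squared = ss_reg / ss_tot, p_value = p_value,
                 residuals = res, n = length(sp), excluded = excluded),
            class = "allometry_fit")
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat("Allometric fit for '", x$trait, "': ln(trait) = ",
      signif(x$intercept, 4), " + ", signif(x$slope, 4),
      " * ln(mass)  (n = ", x$n, ", R^2 = ", signif(x$r_squared, 3), ")\n",
      sep = "")
  invisible(x)
}

#' @method tidy allometry_fit
#' @export
tidy.allometry_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @method glance allometry_fit
#' @export
glance.allometry_fit <- function(x, ...) {
  tibble::tibble(trait = x$trait, n = x$n, r_squared = x$r_squared,
                 p_value = x$p_value)
}

#' Assemble a species-by-trait residual matrix
#'
#' Restricts a list of allometric fits to the retained species, in a given
#' order (typically the pruned tree's tip order).  Pruning happens after the
#' regression — fits must already cover every retained species.
#'
#' @param fits List of `allometry_fit` objects (one per trait).
#' @param keep Character vector of species to retain, in the desired row
#'   order.
#' @return Numeric matrix, species (rows, ordered as `keep`) by traits.
#' @export
residual_matrix <- function(fits, keep) {
  if (inherits(fits, "allometry_fit")) fits <- list(fits)
  cols <- lapply(fits, function(f) {
    miss <- setdiff(keep, names(f$residuals))
    if (length(miss))
      stop("no residuals for species/trait combination: ",
           paste(paste0(miss, "/", f$trait), collapse = ", "), call. = FALSE)
    f$residuals[keep]
  })
  out <- do.call(cbind, cols)
  colnames(out) <- vapply(fits, `[[`, "", "trait")
  rownames(out) <- keep
  out
}

#' Pooled intraspecific standard deviation on the residual scale
#'
#' Pools the within-species variance of ln-trait values across all species
#' measured with at least two specimens.  Because the allometric fit only
#' shifts species means, a ln-scale specimen SD carries over unchanged to
#' the residual scale.
#'
#' @param traits Trait table.
#' @param trait Trait id.
#' @return Pooled SD (0 when no species has replicate specimens).
#' @export
pooled_specimen_sd <- function(traits, trait) {
  tt <- traits[traits$trait == trait, ]
  bysp <- split(tt$value, tt$species)
  bysp <- bysp[lengths(bysp) >= 2]
  if (!length(bysp)) return(0)
  ss <- sum(vapply(bysp, function(v) sum((v - mean(v))^2), 0))
  df <- sum(lengths(bysp) - 1L)
  sqrt(ss / df)
}
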