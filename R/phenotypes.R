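#' @include AllClasses.R AllGenerics.R
NULL

# DFrame subclasses do not support `$<-` directly; modify as DFrame and
# re-wrap (validity is re-checked by the caller where it matters).
.setPhenoCol <- function(p, name, value, validate = TRUE) {
  df <- as(p, "DFrame")
  df[[name]] <- value
  out <- new("PhenotypeTable", df)
  if (validate) validObject(out)
  out
}

#' Construct a PhenotypeTable
#'
#' @param x a data.frame (or DataFrame) with the required columns
#'   `animal_id`, `milk_yield`, `dmi`, `body_weight`, `parity`,
#'   `population`, and any of the optional columns `fat_pct`,
#'   `protein_pct`, `fe`, `rfi`, `group`.
#' @return a [PhenotypeTable-class].
#' @export
PhenotypeTable <- function(x) {
  df <- DataFrame(x, check.names = FALSE)
  df$animal_id <- as.character(df$animal_id)
  df$parity <- as.character(df$parity)
  df$population <- as.character(df$population)
  new("PhenotypeTable", df)
}

#' Read and write phenotype tables
#'
#' Phenotypes are stored as CSV with required headers `animal_id`,
#' `milk_yield`, `dmi`, `body_weight`, `parity`, `population` and optional
#' `fat_pct`, `protein_pct` (plus any derived columns).
#'
#' @param path file path.
#' @return a [PhenotypeTable-class].
#' @export
readPhenotypeTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.PHENO_REQUIRED, colnames(df))
  if (length(missing_cols))
    stop("phenotype file ", path, " lacks required headers: ",
         paste(missing_cols, collapse = ", "))
  PhenotypeTable(df)
}

#' @rdname readPhenotypeTable
#' @param p a [PhenotypeTable-class] to write.
#' @export
writePhenotypeTable <- function(p, path) {
  write.csv(as.data.frame(p), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Derive feed efficiency
#'
#' Feed efficiency (FE) is daily milk yield (kg) divided by dry matter
#' intake (kg): the kilograms of milk produced per kilogram of feed eaten.
#'
#' @param p a [PhenotypeTable-class] with `milk_yield` and `dmi`.
#' @return the table with an `fe` column.
#' @examples
#' p <- PhenotypeTable(data.frame(animal_id = "a", milk_yield = 30, dmi = 20,
#'                                body_weight = 650, parity = "multiparous",
#'                                population = "ref"))
#' deriveFE(p)$fe  # 1.5
#' @export
deriveFE <- function(p) {
  stopifnot(is(p, "PhenotypeTable"))
  if (any(p$dmi <= 0)) stop("dmi must be positive to derive feed efficiency")
  .setPhenoCol(p, "fe", p$milk_yield / p$dmi)
}

#' Derive residual feed intake
#'
#' Residual feed intake (RFI) is observed minus expected dry matter intake,
#' where expected intake is the fit of an ordinary least-squares regression
#' of DMI on production and maintenance traits, estimated separately within
#' each population. The default expected-intake model is
#' `dmi ~ milk_yield + body_weight^0.75` (metabolic body weight). RFI
#' averages exactly zero within each population because the model carries
#' an intercept; lower RFI means a more efficient animal.
#'
#' @param p a [PhenotypeTable-class].
#' @param predictors character vector of predictor specifications; each is
#'   either a column name or `"column^power"` for a power transform.
#' @return the table with an `rfi` column.
#' @export
deriveRFI <- function(p, predictors = c("milk_yield", "body_weight^0.75")) {
  stopifnot(is(p, "PhenotypeTable"), length(predictors) >= 1L)
  design_col <- function(spec) {
    parts <- strsplit(spec, "^", fixed = TRUE)[[1]]
    if (!(parts[1] %in% colnames(p)))
      stop("predictor trait '", parts[1], "' is not present")
    v <- as.numeric(p[[parts[1]]])
    if (length(parts) == 2L) v <- v^as.numeric(parts[2])
    v
  }
  X <- vapply(predictors, design_col, numeric(nrow(p)))
  rfi <- rep(NA_real_, nrow(p))
  for (pop in unique(p$population)) {
    idx <- which(p$population == pop)
    if (length(idx) < 3L)
      stop("population '", pop, "' has fewer than 3 animals")
    Xp <- cbind(1, X[idx, , drop = FALSE])
    if (qr(Xp)$rank < ncol(Xp))
      stop("collinear expected-intake design in population '", pop,
           "' for predictors: ", paste(predictors, collapse = ", "))
    fit <- lm.fit(Xp, p$dmi[idx])
    rfi[idx] <- fit$residuals
  }
  .setPhenoCol(p, "rfi", rfi)
}

#' Assign HIGH/LOW phenotype groups from a trait's extremes
#'
#' Orders animals by the trait and labels the top `nPerTail` as `"HIGH"`,
#' the bottom `nPerTail` as `"LOW"`, and the remainder `"unassigned"`.
#' Ties are broken by stable input order; a tie straddling either cut
#' boundary triggers a warning because the grouping is then order-dependent.
#'
#' @param p a [PhenotypeTable-class].
#' @param trait column to rank on, typically `"fe"` or `"dmi"`.
#' @param nPerTail animals per tail; `2 * nPerTail` must not exceed the
#'   number of animals.
#' @return the table with a `group` column.
#' @export
assignGroups <- function(p, trait = c("fe", "dmi"), nPerTail) {
  stopifnot(is(p, "PhenotypeTable"))
  trait <- match.arg(trait)
  if (!(trait %in% colnames(p)) || anyNA(p[[trait]]))
    stop("trait '", trait, "' must be present and complete")
  nPerTail <- as.integer(nPerTail)
  n <- nrow(p)
  if (2L * nPerTail > n)
    stop("2 * nPerTail (", 2L * nPerTail, ") exceeds the number of animals (", n, ")")
  v <- as.numeric(p[[trait]])
  ord <- order(v, decreasing = TRUE)  # stable: ties keep input order
  group <- rep("unassigned", n)
  group[ord[seq_len(nPerTail)]] <- "HIGH"
  group[ord[seq.int(n - nPerTail + 1L, n)]] <- "LOW"
  boundary_tie <- (nPerTail < n &&
                     v[ord[nPerTail]] == v[ord[nPerTail + 1L]]) ||
                  (nPerTail < n &&
                     v[ord[n - nPerTail + 1L]] == v[ord[n - nPerTail]])
  if (boundary_tie)
    warning("tie in '", trait, "' straddles a group boundary; ",
            "resolved by stable input order")
  .setPhenoCol(p, "group", group)
}
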