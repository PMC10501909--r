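# Species characteristic tables (AnAge-style) and quantities derived from them.

#' Construct a validated species trait table
#'
#' A trait table records, per species, the three life-history traits that
#' drive all age transformations: maximum lifespan, gestation time and age at
#' sexual maturity (ASM), all in years. Tables start out with reported
#' (unadjusted) lifespans; see [adjust_max_lifespan()] for the lifespan
#' inflation applied before relative-age clocks are built.
#'
#' @param df data frame with columns `species_id`, `max_lifespan`,
#'   `gestation_time`, `asm` (years, decimal point).
#' @param exempt character vector of species ids exempt from lifespan
#'   adjustment. Defaults to the two species whose maximum age is considered
#'   reliably established (human and house mouse).
#' @param adjusted logical; whether lifespans in `df` have already been
#'   multiplied by the adjustment factor. Almost always `FALSE` on input.
#' @return A `trait_table`: a data frame with attributes `exempt` and
#'   `lifespan_adjusted`.
#' @seealso [load_trait_table()], [adjust_max_lifespan()]
#' @export
trait_table <- function(df, exempt = c("human", "house mouse"),
                        adjusted = FALSE) {
  required <- c("species_id", "max_lifespan", "gestation_time", "asm")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("trait table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[required]
  df$species_id <- as.character(df$species_id)
  for (col in required[-1]) df[[col]] <- as.numeric(df[[col]])

  dup <- unique(df$species_id[duplicated(df$species_id)])
  if (length(dup) > 0L) {
    stop("duplicate species_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  bad <- !is.finite(df$max_lifespan) | !is.finite(df$gestation_time) |
    !is.finite(df$asm) | df$max_lifespan <= 0 | df$gestation_time <= 0 |
    df$asm <= 0 | df$asm >= df$max_lifespan
  if (any(bad)) {
    stop("invalid trait rows (need max_lifespan > asm > 0 and ",
         "gestation_time > 0): ",
         paste(df$species_id[bad], collapse = ", "), call. = FALSE)
  }
  structure(df,
            exempt = as.character(exempt),
            lifespan_adjusted = isTRUE(adjusted),
            class = c("trait_table", "data.frame"))
}

#' Load a species trait table from a delimited file
#'
#' Reads a CSV/TSV file with header `species_id,max_lifespan,gestation_time,asm`
#' (years). Lines starting with `#` are ignored. Rows violating the trait
#' invariants are rejected with a per-row report.
#'
#' @param path file path.
#' @param exempt species ids exempt from lifespan adjustment.
#' @param sep field separator; `","` by default, auto-detects tab when the
#'   header contains none of the default separator.
#' @return A [trait_table()].
#' @export
load_trait_table <- function(path, exempt = c("human", "house mouse"),
                             sep = ",") {
  if (!file.exists(path)) stop("trait table not found: ", path, call. = FALSE)
  header <- readLines(path, n = 25L)
  header <- header[!startsWith(header, "#")][1]
  if (!grepl(sep, header, fixed = TRUE) && grepl("\t", header, fixed = TRUE)) {
    sep <- "\t"
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", stringsAsFactors = FALSE)
  trait_table(df, exempt = exempt)
}

#' Resolve one species' trait record
#'
#' @param table a [trait_table()].
#' @param species_id single species id.
#' @return One-row `trait_table` keeping the adjustment flag.
#' @export
species_traits <- function(table, species_id) {
  stopifnot(inherits(table, "trait_table"), length(species_id) == 1L)
  i <- match(species_id, table$species_id)
  if (is.na(i)) stop("unknown species: ", species_id, call. = FALSE)
  out <- table[i, , drop = FALSE]
  attr(out, "exempt") <- attr(table, "exempt")
  attr(out, "lifespan_adjusted") <- attr(table, "lifespan_adjusted")
  class(out) <- c("trait_table", "data.frame")
  out
}

#' Inflate reported maximum lifespans
#'
#' The evidence behind the recorded maximum age is very uneven across
#' species: humans and laboratory mice have been observed in the billions and
#' millions, other species far less. To compensate, the reported maximum
#' lifespan of every non-exempt species is multiplied by 1.3 (a 30% upward
#' allowance) before relative age is computed; the exempt species (by default
#' human, 122.5 years, and house mouse, 4 years) keep their reported values.
#'
#' @param table an unadjusted [trait_table()].
#' @param multiplier positive inflation factor (default 1.3).
#' @return The adjusted `trait_table` with `lifespan_adjusted = TRUE`.
#'   Adjusting twice is an error.
#' @export
adjust_max_lifespan <- function(table, multiplier = 1.3) {
  stopifnot(inherits(table, "trait_table"), is.numeric(multiplier),
            length(multiplier) == 1L, multiplier > 0)
  if (isTRUE(attr(table, "lifespan_adjusted"))) {
    stop("trait table is already lifespan-adjusted", call. = FALSE)
  }
  exempt <- attr(table, "exempt")
  scale <- ifelse(table$species_id %in% exempt, 1, multiplier)
  table$max_lifespan <- table$max_lifespan * scale
  attr(table, "lifespan_adjusted") <- TRUE
  table
}

#' Log-lifespan ratios relative to a reference species
#'
#' Divides the natural log of each species' maximum lifespan by the log of a
#' reference species' lifespan, so the reference maps to exactly 1 and
#' shorter-lived species map into (0, 1). Reported (unadjusted) lifespans are
#' the intended input: with the reference at 211 years (bowhead whale), a
#' 122.5-year human gives 0.90. The ratio is invariant to the log base.
#'
#' @param table a [trait_table()]; pass the unadjusted table.
#' @param reference_species species id of the denominator species.
#' @return Named numeric vector of ratios, one per species.
#' @export
log_lifespan_ratio <- function(table, reference_species) {
  stopifnot(inherits(table, "trait_table"))
  ref <- species_traits(table, reference_species)
  if (ref$max_lifespan <= 1) {
    stop("reference lifespan must exceed 1 year (log denominator <= 0)",
         call. = FALSE)
  }
  out <- log(table$max_lifespan) / log(ref$max_lifespan)
  names(out) <- table$species_id
  out
}

#' Allometric regression of lifespan ratio on gestation/maturity ratio
#'
#' Fits, by ordinary least squares across species,
#' `log((MaxLifespan + GestationT) / (ASM + GestationT))` on
#' `log(GestationT / ASM)` (natural logs). Across real mammals this relation
#' is approximately `2.92 + 0.38 * log(GestationT/ASM)` with a moderate
#' correlation (about 0.5) between the two log variables; it underpins the
#' lifespan-free change point of the log-linear clock (see
#' [estimate_m_hat()]).
#'
#' @param table a [trait_table()] with at least 3 species.
#' @return List with `intercept`, `slope`, `correlation` (Pearson correlation
#'   of the two log variables) and `n`.
#' @export
fit_allometric_surrogate <- function(table) {
  stopifnot(inherits(table, "trait_table"))
  keep <- stats::complete.cases(table[c("max_lifespan", "gestation_time",
                                        "asm")])
  if (sum(keep) < nrow(table)) {
    warning(sum(!keep), " species with incomplete traits excluded from the ",
            "allometric fit")
  }
  t2 <- table[keep, , drop = FALSE]
  if (nrow(t2) < 2L) stop("need at least 2 complete species", call. = FALSE)
  x <- log(t2$gestation_time / t2$asm)
  y <- log((t2$max_lifespan + t2$gestation_time) /
             (t2$asm + t2$gestation_time))
  if (stats::var(x) == 0) {
    stop("degenerate fit: zero variance in log(gestation/asm)", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  list(intercept = unname(fit$coefficients[1]),
       slope = unname(fit$coefficients[2]),
       correlation = stats::cor(x, y),
       n = nrow(t2))
}

#' Change point of the log-linear age transformation
#'
#' Estimates the species-specific change point `m` of the log-linear clock
#' without using maximum lifespan:
#' `m_hat = c2 * (GestationT / ASM) ^ exponent`, with `c2 = 5.0` and
#' exponent 0.38 taken from the cross-species allometric regression
#' ([fit_allometric_surrogate()]). `m_hat` is strictly increasing in
#' gestation time and strictly decreasing in ASM.
#'
#' @param traits a [trait_table()] (any number of rows).
#' @param c2 positive scale constant (default 5.0).
#' @param exponent allometric exponent (default 0.38).
#' @return Named numeric vector of change points, one per species.
#' @export
estimate_m_hat <- function(traits, c2 = 5.0, exponent = 0.38) {
  stopifnot(is.data.frame(traits), c2 > 0)
  ratio <- traits$gestation_time / traits$asm
  if (any(!is.finite(ratio) | ratio <= 0)) {
    stop("gestation_time/asm must be positive and finite", call. = FALSE)
  }
  out <- c2 * ratio^exponent
  names(out) <- traits$species_id
  out
}
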