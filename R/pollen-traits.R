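#' Construct a single pollen sample
#'
#' A pollen sample is the scopal load of one female bee: a composition of
#' named pollen types (percentages summing to 100 within +/- 1) together
#' with a positive load-size weight, the original size class of the pollen
#' load assigned before pollen removal.  Percentages in heterogeneous loads
#' are corrected by this weight when samples are aggregated per species.
#'
#' @param species Species label.
#' @param sample_id Sample identifier.
#' @param composition Named numeric vector of percentages (sums to 100
#'   within +/- 1; entries >= 0).
#' @param load_weight Positive load-size weight; defaults to 1, appropriate
#'   for literature-derived records that carry no load size.
#' @return An object of class `pollen_sample`.
#' @export
pollen_sample <- function(species, sample_id, composition, load_weight = 1) {
  stopifnot(is.numeric(composition), length(composition) >= 1L,
            !is.null(names(composition)))
  if (any(composition < 0)) stop("percentages must be >= 0", call. = FALSE)
  s <- sum(composition)
  if (s < 99 || s > 101) {
    stop("composition of sample '", sample_id, "' sums to ", signif(s, 6),
         ", outside [99, 101]", call. = FALSE)
  }
  if (!is.finite(load_weight) || load_weight <= 0) {
    stop("load_weight must be > 0", call. = FALSE)
  }
  structure(list(species = as.character(species),
                 sample_id = as.character(sample_id),
                 load_weight = load_weight,
                 composition = composition),
            class = "pollen_sample")
}

#' Read a pollen sample table
#'
#' Long-format CSV/TSV with columns `species`, `sample_id`, `load_weight`,
#' `pollen_type`, `percent` (one row per pollen type per sample).  A missing
#' or NA `load_weight` defaults to 1.
#'
#' @param file Path to the table.
#' @param sep Field separator; inferred from the extension by default.
#' @return A list of [pollen_sample()] objects.
#' @export
read_pollen_table <- function(file, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", file)) "\t" else ","
  d <- utils::read.table(file, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  req <- c("species", "sample_id", "pollen_type", "percent")
  if (!all(req %in% names(d))) {
    stop("pollen table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(d$load_weight)) d$load_weight <- 1
  d$load_weight[is.na(d$load_weight)] <- 1
  keys <- paste(d$species, d$sample_id, sep = "\r")
  lapply(split(d, keys), function(g) {
    comp <- stats::setNames(g$percent, g$pollen_type)
    pollen_sample(g$species[1L], g$sample_id[1L], comp, g$load_weight[1L])
  })
}

#' Read a pollen-type catalog
#'
#' CSV with columns `pollen_type`, `plant_family`, `accessibility`
#' (`accessible`, `restricted`, or `unknown`); an optional `plant_genus`
#' column enables genus-level specificity classification.
#'
#' @param file Path to the catalog CSV.
#' @return A `pollen_catalog`: a data frame keyed by pollen type.
#' @export
read_pollen_catalog <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  pollen_catalog(d)
}

#' @rdname read_pollen_catalog
#' @param df Data frame with the catalog columns.
#' @export
pollen_catalog <- function(df) {
  req <- c("pollen_type", "plant_family", "accessibility")
  if (!all(req %in% names(df))) {
    stop("catalog must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  ok <- c("accessible", "restricted", "unknown")
  if (!all(df$accessibility %in% ok)) {
    stop("accessibility must be one of: ", paste(ok, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$pollen_type)) {
    stop("duplicate pollen_type entries in catalog", call. = FALSE)
  }
  rownames(df) <- df$pollen_type
  class(df) <- c("pollen_catalog", "data.frame")
  df
}

catalog_lookup <- function(catalog, types, field) {
  out <- rep(NA_character_, length(types))
  hit <- types %in% rownames(catalog)
  out[hit] <- catalog[types[hit], field]
  out
}

# Drop pollen types below the minor-type threshold and renormalise.
# Shares strictly below the threshold are excluded ("less than 5%"), so a
# type at exactly the threshold is retained.  Idempotent: a renormalised
# composition whose entries were all >= thr keeps them >= thr.
filter_minor_types <- function(prop, minor_threshold) {
  keep <- prop >= minor_threshold
  if (!any(keep)) return(prop[0])
  p <- prop[keep]
  p / sum(p)
}

#' Aggregate pollen samples into a species-level profile
#'
#' Implements the contamination-robust aggregation used for trait coding:
#' within each sample, pollen types comprising less than `minor_threshold`
#' of the load are excluded (guarding against contamination) and the rest
#' renormalised; samples are then combined as a weighted mean with weights
#' proportional to the original load sizes; finally types whose aggregate
#' share still falls below the threshold are dropped and the profile
#' renormalised, so every retained type exceeds the threshold.
#'
#' @param samples A list of [pollen_sample()] objects, all from one species.
#' @param minor_threshold Minor-type exclusion threshold as a fraction
#'   (default 0.05, i.e. the 5% contamination rule).
#' @return A `species_profile`: list with `species`, `proportions` (named
#'   fractions summing to 1), `n_samples`.
#' @examples
#' s <- pollen_sample("bee1", "a", c(FabR = 60, AstA = 36, BraA = 4))
#' aggregate_species_profile(list(s))$proportions
#' @export
aggregate_species_profile <- function(samples, minor_threshold = 0.05) {
  stopifnot(length(samples) >= 1L)
  if (inherits(samples, "pollen_sample")) samples <- list(samples)
  sp <- unique(vapply(samples, function(s) s$species, ""))
  if (length(sp) != 1L) {
    stop("input error: samples mix species: ", paste(sp, collapse = ", "),
         call. = FALSE)
  }
  filtered <- lapply(samples, function(s) {
    filter_minor_types(s$composition / sum(s$composition), minor_threshold)
  })
  keep <- vapply(filtered, length, 1L) > 0L
  if (!any(keep)) {
    stop("empty profile: all pollen types filtered out for species '", sp,
         "'", call. = FALSE)
  }
  filtered <- filtered[keep]
  w <- vapply(samples[keep], function(s) s$load_weight, 1)
  w <- w / sum(w)
  types <- unique(unlist(lapply(filtered, names)))
  agg <- stats::setNames(numeric(length(types)), types)
  for (i in seq_along(filtered)) {
    agg[names(filtered[[i]])] <- agg[names(filtered[[i]])] +
      w[i] * filtered[[i]]
  }
  agg <- filter_minor_types(agg, minor_threshold)
  if (length(agg) == 0L) {
    stop("empty profile: all pollen types filtered out for species '", sp,
         "'", call. = FALSE)
  }
  structure(list(species = sp,
                 proportions = sort(agg, decreasing = TRUE),
                 n_samples = length(samples)),
            class = "species_profile")
}

#' @export
print.species_profile <- function(x, ...) {
  cat("species profile:", x$species, sprintf("(%d samples)\n", x$n_samples))
  print(round(x$proportions, 4))
  invisible(x)
}

#' Classify a species' pollen-host accessibility
#'
#' Returns `"A"` when every retained pollen type is accessible, `"R"` when
#' every type is restricted, `"AR"` (polymorphic) when both categories are
#' carried with each category's total share above `minor_threshold` of the
#' aggregate, and `"data_deficient"` when types of unknown accessibility
#' exceed that threshold.  A minority category at or below the threshold is
#' treated as noise, mirroring the contamination rule used per sample.
#'
#' @param profile A `species_profile`.
#' @param catalog A `pollen_catalog`.
#' @param minor_threshold Share below which a category is ignored
#'   (default 0.05).
#' @return One of `"A"`, `"R"`, `"AR"`, `"data_deficient"`.
#' @export
classify_accessibility <- function(profile, catalog, minor_threshold = 0.05) {
  stopifnot(inherits(profile, "species_profile"))
  p <- profile$proportions
  if (length(p) == 0L) stop("empty profile", call. = FALSE)
  acc <- catalog_lookup(catalog, names(p), "accessibility")
  acc[is.na(acc)] <- "unknown"
  share <- function(cls) sum(p[acc == cls])
  if (share("unknown") > minor_threshold) return("data_deficient")
  a <- share("accessible"); r <- share("restricted")
  if (a > minor_threshold && r > minor_threshold) return("AR")
  if (a >= r) "A" else "R"
}

#' Classify a species as pollen specialist or generalist
#'
#' A species is a specialist (oligolectic) when at least `threshold` of the
#' pollen it carries belongs to a single plant family (or genus, when
#' `level = "genus"` and the catalog has a `plant_genus` column); the
#' boundary is inclusive (exactly 95% counts as specialist).
#'
#' @param profile A `species_profile`.
#' @param catalog A `pollen_catalog`.
#' @param threshold Specialist threshold as a fraction (default 0.95).
#' @param level `"family"` (default) or `"genus"`.
#' @return `"specialist"`, `"generalist"`, or `"data_deficient"` when
#'   retained types cannot be resolved at the requested level.
#' @export
classify_specificity <- function(profile, catalog, threshold = 0.95,
                                 level = c("family", "genus")) {
  level <- match.arg(level)
  stopifnot(inherits(profile, "species_profile"))
  p <- profile$proportions
  field <- if (level == "family") "plant_family" else "plant_genus"
  if (level == "genus" && is.null(catalog[["plant_genus"]])) {
    stop("catalog has no plant_genus column", call. = FALSE)
  }
  grp <- catalog_lookup(catalog, names(p), field)
  if (anyNA(grp) || any(!nzchar(grp))) return("data_deficient")
  shares <- tapply(p, grp, sum)
  if (max(shares) >= threshold) "specialist" else "generalist"
}

#' Code species states into a binary character matrix
#'
#' Maps categorical accessibility or specificity states onto the four named
#' binary partitions:
#' \describe{
#'   \item{PA1}{accessible = 0, restricted = 1, polymorphic AR scored 1
#'     (restricted).}
#'   \item{PA2}{as PA1 but AR treated as ambiguous.}
#'   \item{PA3}{as PA1 but AR scored 0 (accessible).}
#'   \item{PS}{specialist = 0, generalist = 1.}
#' }
#' `data_deficient` species are coded missing in every partition.
#'
#' @param states Named character vector: species to state, states in
#'   `A/R/AR/data_deficient` (PA partitions) or
#'   `specialist/generalist/data_deficient` (PS).
#' @param partition One of `"PA1"`, `"PA2"`, `"PA3"`, `"PS"`.
#' @param tip_labels Optional full set of tree tips; tips absent from
#'   `states` are coded missing.
#' @return A `character_matrix`: list with `partition` and `states`, a named
#'   vector over tips with values `"0"`, `"1"`, `"ambiguous"`, `"missing"`.
#' @export
build_character_matrix <- function(states, partition = c("PA1", "PA2", "PA3", "PS"),
                                   tip_labels = names(states)) {
  partition <- match.arg(partition)
  stopifnot(!is.null(names(states)))
  pa_map <- list(PA1 = c(A = "0", R = "1", AR = "1", data_deficient = "missing"),
                 PA2 = c(A = "0", R = "1", AR = "ambiguous",
                         data_deficient = "missing"),
                 PA3 = c(A = "0", R = "1", AR = "0", data_deficient = "missing"),
                 PS = c(specialist = "0", generalist = "1",
                        data_deficient = "missing"))
  map <- pa_map[[partition]]
  bad <- setdiff(unique(states), names(map))
  if (length(bad)) {
    stop("input error: states not legal for partition ", partition, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- stats::setNames(rep("missing", length(tip_labels)), tip_labels)
  known <- intersect(tip_labels, names(states))
  out[known] <- unname(map[states[known]])
  structure(list(partition = partition, states = out),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  tab <- table(factor(x$states, levels = c("0", "1", "ambiguous", "missing")))
  cat("character matrix, partition", x$partition, "-",
      length(x$states), "tips:\n")
  print(tab)
  invisible(x)
}

#' Write a character matrix to CSV or a NEXUS characters block
#'
#' @param x A `character_matrix`.
#' @param file Output path.
#' @param format `"csv"` or `"nexus"`.  NEXUS uses `0`, `1`, `{01}` for
#'   ambiguous and `?` for missing.
#' @return `file`, invisibly.
#' @export
write_character_matrix <- function(x, file, format = c("csv", "nexus")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "character_matrix"))
  if (format == "csv") {
    utils::write.csv(data.frame(species = names(x$states),
                                partition = x$partition,
                                state = unname(x$states)),
                     file, row.names = FALSE)
  } else {
    sym <- c("0" = "0", "1" = "1", ambiguous = "{01}", missing = "?")
    lab <- gsub("[^A-Za-z0-9_.]", "_", names(x$states))
    lines <- c("#NEXUS", "BEGIN CHARACTERS;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=1;", length(x$states)),
               "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=? GAP=-;",
               "  MATRIX",
               sprintf("    %s %s", format(lab), sym[x$states]),
               "  ;", "END;")
    writeLines(lines, file)
  }
  invisible(file)
}

#' Code a full pollen dataset into species states
#'
#' Convenience wrapper: groups samples by species, aggregates profiles, and
#' classifies accessibility and specificity for each species.
#'
#' @param samples List of [pollen_sample()] objects (multiple species).
#' @param catalog A `pollen_catalog`.
#' @param minor_threshold Minor-type threshold (default 0.05).
#' @param specificity_threshold Specialist threshold (default 0.95).
#' @return Data frame with columns `species`, `n_samples`, `accessibility`,
#'   `specificity`.
#' @export
code_pollen_dataset <- function(samples, catalog, minor_threshold = 0.05,
                                specificity_threshold = 0.95) {
  sp <- vapply(samples, function(s) s$species, "")
  by_sp <- split(samples, sp)
  rows <- lapply(names(by_sp), function(nm) {
    prof <- aggregate_species_profile(by_sp[[nm]], minor_threshold)
    data.frame(species = nm, n_samples = prof$n_samples,
               accessibility = classify_accessibility(prof, catalog,
                                                      minor_threshold),
               specificity = classify_specificity(prof, catalog,
                                                  specificity_threshold),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
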