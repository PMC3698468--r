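#' @name survey
#' @title Survey ingestion: quadrat records, plot composition, plant records
#'
#' @description
#' The field design: each plot is surveyed with 4 one-square-meter quadrats;
#' a species' plot-level abundance is the number of quadrats (0-4) in which
#' it occurs. Herbivory is recorded per individual plant as damaged leaves
#' out of total leaves. These functions read, validate, and aggregate those
#' tables into the model's inputs.
NULL

sep_for <- function(file) if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"

read_checked <- function(file, int_cols = character()) {
  df <- read.table(file, header = TRUE, sep = sep_for(file),
                   colClasses = "character", stringsAsFactors = FALSE,
                   fileEncoding = "UTF-8", check.names = FALSE)
  for (cl in int_cols) {
    if (!cl %in% names(df)) stop("missing required column '", cl, "' in ", file)
    bad <- !grepl("^-?[0-9]+$", df[[cl]])
    if (any(bad))
      stop("non-integer value(s) in column '", cl, "' of ", file, ": ",
           paste(utils::head(unique(df[[cl]][bad]), 3), collapse = ", "))
    df[[cl]] <- as.integer(df[[cl]])
  }
  df
}

#' Read a quadrat survey file
#'
#' Expected columns: `plot`, `quadrat` (1-4), `species`. One row per species
#' per quadrat in which it was seen.
#'
#' @param file CSV or TSV path (UTF-8, header row required).
#' @return validated data frame of quadrat records.
#' @export
read_quadrat_table <- function(file) {
  df <- read_checked(file, int_cols = "quadrat")
  need <- c("plot", "quadrat", "species")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  validate_quadrats(df[need])
}

validate_quadrats <- function(records) {
  if (any(!records$quadrat %in% 1:4))
    stop("quadrat index out of range 1-4")
  if (any(!nzchar(records$species))) stop("empty species name")
  # no species duplicated within one quadrat, <= 4 quadrats per plot
  key <- paste(records$plot, records$quadrat, records$species, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (plot, quadrat, species) record")
  nq <- tapply(records$quadrat, records$plot, function(q) length(unique(q)))
  if (any(nq > 4)) stop("more than 4 quadrats in plot(s): ",
                        paste(names(nq)[nq > 4], collapse = ", "))
  records
}

#' Aggregate quadrat presence into plot-level 0-4 abundances
#'
#' A species' abundance in a plot is the number of quadrats of that plot in
#' which it occurred (a low-resolution abundance measure ranging 0-4).
#' Absent species are omitted from the sparse long-format table.
#'
#' @param records data frame with columns `plot`, `quadrat`, `species`.
#' @return long-format composition data frame: `plot`, `species`, `abundance`.
#' @export
aggregate_quadrats <- function(records) {
  records <- validate_quadrats(records)
  agg <- stats::aggregate(list(abundance = records$quadrat),
                          by = list(plot = records$plot, species = records$species),
                          FUN = function(q) length(unique(q)))
  agg <- agg[order(agg$plot, agg$species), c("plot", "species", "abundance")]
  rownames(agg) <- NULL
  validate_composition(agg)
}

validate_composition <- function(composition) {
  need <- c("plot", "species", "abundance")
  miss <- setdiff(need, names(composition))
  if (length(miss)) stop("composition missing column(s): ", paste(miss, collapse = ", "))
  a <- composition$abundance
  if (any(a != round(a)) || any(a < 0) || any(a > 4))
    stop("abundances must be integers in 0-4")
  if (anyDuplicated(paste(composition$plot, composition$species, sep = "\r")))
    stop("duplicate (plot, species) row in composition")
  pres <- tapply(a, composition$plot, function(x) sum(x >= 1))
  if (any(pres < 1)) stop("plot(s) with no species present: ",
                          paste(names(pres)[pres < 1], collapse = ", "))
  composition
}

#' Species richness of a plot composition
#'
#' Number of species with abundance >= 1. Counts all surveyed species,
#' not only those for which herbivory was measured.
#'
#' @param composition long composition data frame (one or many plots).
#' @return named integer vector, one entry per plot.
#' @export
species_richness <- function(composition) {
  composition <- validate_composition(composition)
  out <- tapply(composition$abundance, composition$plot, function(a) sum(a >= 1))
  setNames(as.integer(out), names(out))
}

#' Read / write long-format composition tables
#'
#' Columns: `plot`, `species`, `abundance` (integer 0-4).
#' @param file CSV or TSV path.
#' @export
read_composition_table <- function(file) {
  df <- read_checked(file, int_cols = "abundance")
  validate_composition(df[c("plot", "species", "abundance")])
}

#' @rdname read_composition_table
#' @param composition composition data frame.
#' @export
write_composition_table <- function(composition, file) {
  write.table(validate_composition(composition), file, sep = sep_for(file),
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(file)
}

#' Read a per-plant herbivory file
#'
#' Expected columns: `plot`, `species`, `damaged`, `total` — one row per
#' individual plant, counting damaged leaves out of total leaves.
#'
#' @param file CSV or TSV path.
#' @return validated data frame of plant observations.
#' @export
read_plant_table <- function(file) {
  df <- read_checked(file, int_cols = c("damaged", "total"))
  need <- c("plot", "species", "damaged", "total")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  validate_plants(df[need])
}

validate_plants <- function(plants) {
  if (any(plants$total < 1)) stop("total leaves must be >= 1")
  if (any(plants$damaged < 0) || any(plants$damaged > plants$total))
    stop("damaged must satisfy 0 <= damaged <= total")
  plants
}

#' Read a plot sampling-date file
#'
#' Columns: `plot`, `date` (integer day offset from the first sampling day).
#' @param file CSV or TSV path.
#' @export
read_date_table <- function(file) {
  df <- read_checked(file, int_cols = "date")
  if (!all(c("plot", "date") %in% names(df))) stop("need columns plot, date")
  if (anyDuplicated(df$plot)) stop("duplicate plot in date table")
  df[c("plot", "date")]
}

#' Build the centered plot-level predictor table
#'
#' Assembles per-plot SR, PD (PSE), and DATE; centers each by subtracting its
#' mean (stored for back-prediction), and forms the interaction column as the
#' product of the *centered* main effects. The interaction is not itself
#' re-centered, so each main effect is the slope at the mean of the other
#' variables.
#'
#' @param diversity data frame with columns `plot`, `SR`, `PSE`
#'   (from [plot_diversity()]).
#' @param dates data frame with columns `plot`, `date`.
#' @return data frame of class `"herb_predictors"` with original and centered
#'   (`*_c`) columns plus the interaction `SRPD_c`; centering means in
#'   `attr(, "means")`, observed ranges in `attr(, "ranges")`.
#' @export
build_predictors <- function(diversity, dates) {
  need <- c("plot", "SR", "PSE")
  miss <- setdiff(need, names(diversity))
  if (length(miss)) stop("diversity table missing: ", paste(miss, collapse = ", "))
  if (anyDuplicated(diversity$plot)) stop("duplicate plot in diversity table")
  no_date <- setdiff(diversity$plot, dates$plot)
  if (length(no_date)) stop("no sampling date for plot(s): ",
                            paste(no_date, collapse = ", "))
  drop_na <- is.na(diversity$PSE)
  if (any(drop_na)) {
    warning("excluding plot(s) with undefined PSE: ",
            paste(diversity$plot[drop_na], collapse = ", "))
    diversity <- diversity[!drop_na, ]
  }
  tab <- merge(diversity[need], dates[c("plot", "date")], by = "plot")
  tab <- tab[order(tab$plot), ]
  names(tab)[names(tab) == "PSE"] <- "PD"
  names(tab)[names(tab) == "date"] <- "DATE"
  means <- c(SR = mean(tab$SR), PD = mean(tab$PD), DATE = mean(tab$DATE))
  tab$SR_c <- tab$SR - means["SR"]
  tab$PD_c <- tab$PD - means["PD"]
  tab$DATE_c <- tab$DATE - means["DATE"]
  tab$SRPD_c <- tab$SR_c * tab$PD_c
  rownames(tab) <- NULL
  attr(tab, "means") <- means
  attr(tab, "ranges") <- list(SR = range(tab$SR), PD = range(tab$PD),
                              DATE = range(tab$DATE))
  class(tab) <- c("herb_predictors", "data.frame")
  tab
}

#' Pielou evenness of a plot's 0-4 abundances (utility)
#'
#' Shannon entropy of the relative abundances divided by `log(SR)`. Provided
#' for exploratory use only; evenness is not part of the damage model. The
#' choice of Pielou's index here is a convention of this package.
#'
#' @param m non-negative abundance vector for one plot.
#' @return evenness in `[0, 1]`, or `NA` when fewer than 2 species present.
#' @export
pielou_evenness <- function(m) {
  m <- m[m > 0]
  if (length(m) < 2L) return(NA_real_)
  q <- m / sum(m)
  H <- -sum(q * log(q))
  H / log(length(m))
}
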