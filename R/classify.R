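# Retailer classification under the two index schemes.
#
# The activity-based scheme (rfai_2017) uses 2017 NAICS codes and ignores
# employment size: supermarkets and grocery stores (445110), warehouse clubs
# (452311) and fruit and vegetable retailers (445230) are healthy;
# convenience stores (445120) and limited-service restaurants (722513) are
# less healthy. The location-based scheme (mrfei_2007) uses 2007 NAICS codes
# and an employee-size rule for 445110: >= 10 employees healthy (supermarkets
# >= 50, larger grocery 10-49), <= 3 less healthy (small grocery), 4-9 or
# unknown excluded; warehouse clubs are 452910 and limited-service
# restaurants 722211 in that vintage.

rfai_healthy <- c("445110", "452311", "445230")
rfai_less_healthy <- c("445120", "722513")
mrfei_healthy <- c("452910", "445230")
mrfei_less_healthy <- c("722211", "445120")

# the only code pairs that renumber between the 2007 and 2017 vintages
naics_crosswalk <- data.frame(
  naics_2007 = c("452910", "722211"),
  naics_2017 = c("452311", "722513"),
  stringsAsFactors = FALSE
)

naics_labels <- c(
  "445110" = "supermarkets and grocery stores",
  "445120" = "convenience stores",
  "445230" = "fruit and vegetable retailers",
  "452311" = "warehouse clubs",
  "452910" = "warehouse clubs",
  "722211" = "limited-service restaurants",
  "722513" = "limited-service restaurants"
)

check_naics <- function(naics_code) {
  naics_code <- as.character(naics_code)
  bad <- which(!grepl("^[0-9]{6}$", naics_code))
  if (length(bad))
    stop("malformed NAICS code '", naics_code[bad[1]], "'", call. = FALSE)
  naics_code
}

category_label <- function(naics_code) {
  lab <- unname(naics_labels[naics_code])
  ifelse(is.na(lab), paste("NAICS", naics_code), lab)
}

#' Classify retailers under the activity-based (RFAI) scheme
#'
#' Pure function of the 2017 NAICS code; employment size is ignored, so all
#' supermarkets and grocery stores count as healthy.
#'
#' @param naics_code character vector of 6-digit NAICS codes.
#' @param employee_count ignored; present for interface symmetry.
#' @return factor with levels `healthy`, `less_healthy`, `excluded`.
#' @export
classify_rfai <- function(naics_code, employee_count = NULL) {
  naics_code <- check_naics(naics_code)
  out <- rep("excluded", length(naics_code))
  out[naics_code %in% rfai_healthy] <- "healthy"
  out[naics_code %in% rfai_less_healthy] <- "less_healthy"
  factor(out, levels = c("healthy", "less_healthy", "excluded"))
}

#' Classify retailers under the location-based (mRFEI) scheme
#'
#' Pure function of the 2007 NAICS code and employee count. Grocery stores
#' (445110) with 4-9 employees fall between the two printed rules and are
#' excluded, as are 445110 stores with an unknown employee count.
#'
#' @param naics_code character vector of 6-digit NAICS codes.
#' @param employee_count nonnegative integer vector, `NA` allowed.
#' @return factor with levels `healthy`, `less_healthy`, `excluded`.
#' @export
classify_mrfei <- function(naics_code, employee_count = NA_real_) {
  naics_code <- check_naics(naics_code)
  employee_count <- rep_len(as.numeric(employee_count), length(naics_code))
  out <- rep("excluded", length(naics_code))
  out[naics_code %in% mrfei_healthy] <- "healthy"
  out[naics_code %in% mrfei_less_healthy] <- "less_healthy"
  g <- naics_code == "445110"
  out[g & !is.na(employee_count) & employee_count >= 10] <- "healthy"
  out[g & !is.na(employee_count) & employee_count <= 3] <- "less_healthy"
  # 445110 with 4-9 or missing employees stays excluded
  factor(out, levels = c("healthy", "less_healthy", "excluded"))
}

#' Classification table for a POI set
#'
#' Maps every POI to its retailer class under the named scheme and reports
#' class totals. An optional YAML override file may remap NAICS codes:
#'
#' ```yaml
#' rfai_2017:
#'   "445299": healthy
#' mrfei_2007:
#'   "722515": less_healthy
#' ```
#'
#' @param pois POI data.frame (columns `poi_id`, `naics_code`,
#'   `employee_count`).
#' @param scheme `"rfai_2017"` or `"mrfei_2007"`.
#' @param overrides optional path to a YAML override file, or a named list.
#' @return data.frame `poi_id`, `scheme`, `retailer_class`, `category_label`.
#' @export
classification_table <- function(pois, scheme = c("rfai_2017", "mrfei_2007"),
                                 overrides = NULL) {
  scheme <- match.arg(scheme)
  naics <- check_naics(pois$naics_code)
  cls <- if (scheme == "rfai_2017") classify_rfai(naics)
         else classify_mrfei(naics, pois$employee_count)
  if (!is.null(overrides)) {
    ov <- if (is.character(overrides)) yaml::read_yaml(overrides) else overrides
    ov <- ov[[scheme]]
    if (!is.null(ov)) {
      for (code in names(ov)) {
        cl <- as.character(ov[[code]])
        if (!cl %in% levels(cls))
          stop("override for NAICS ", code, ": unknown class '", cl, "'", call. = FALSE)
        cls[naics == code] <- cl
      }
    }
  }
  counts <- table(cls)
  fe_log("classification (", scheme, "): ",
         paste(names(counts), counts, sep = "=", collapse = ", "))
  if (counts[["healthy"]] + counts[["less_healthy"]] == 0L)
    warning("no qualified retailers under scheme ", scheme, call. = FALSE)
  data.frame(poi_id = as.character(pois$poi_id), scheme = scheme,
             retailer_class = cls, category_label = category_label(naics),
             stringsAsFactors = FALSE)
}
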