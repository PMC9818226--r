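#' Reference dataset: volatile compounds of young and mature Docynia
#' delavayi fruit
#'
#' A curated 42-compound GC-MS volatile panel for *Docynia delavayi* fruit
#' at two maturity stages, young (`DY`) and mature (`DM`), with group-mean
#' relative contents (percent of total peak area). Six compounds (butyl
#' butanoate, butyl hexanoate, hexyl hexanoate, benzylcarbinyl caproate,
#' cis-\eqn{\alpha}-bergamotene, cis-bisabolene) occur only in the mature
#' fruit and carry `detected = FALSE` in DY. Because only group means are
#' available, each group is represented by a single pseudo-replicate whose
#' "areas" are the mean relative contents; [relative_content()] is
#' scale-invariant, so every downstream ratio-based quantity (class
#' shares, rOAV) is unaffected by this encoding. Library match scores are
#' absent (`NA`), so [filter_by_match_score()] retains all compounds with
#' a warning unless run in strict mode.
#'
#' @return `docynia_peak_table()`: a [peak_table()], 42 compounds x 2
#'   pseudo-replicate samples (`DY_1`, `DM_1`).
#' @export
#' @examples
#' pt <- docynia_peak_table()
#' count_detected(pt, "DY")
#' count_detected(pt, "DM")
docynia_peak_table <- function() {
  d <- docynia_compound_data()
  areas <- cbind(DY_1 = d$dy, DM_1 = d$dm)
  areas[is.na(areas)] <- 0
  peak_table(
    compounds = d[, c("id", "name", "cas", "formula", "class", "rt_min")],
    areas = areas,
    groups = c(DY_1 = "DY", DM_1 = "DM"),
    detected = cbind(DY_1 = !is.na(d$dy), DM_1 = !is.na(d$dm))
  )
}

#' @rdname docynia_peak_table
#' @return `docynia_relative_content()`: a `relative_content` view built
#'   directly from the tabulated group-mean percentages (no
#'   renormalisation), so sums of means reproduce the tabulated class
#'   totals at their printed precision. Per-sample sums deviate from 100
#'   by up to ~0.03% (rounding of the source values); the constructor
#'   tolerance reflects that.
#' @export
docynia_relative_content <- function() {
  d <- docynia_compound_data()
  percent <- cbind(DY_1 = replace(d$dy, is.na(d$dy), 0),
                   DM_1 = replace(d$dm, is.na(d$dm), 0))
  cmp <- d[, c("id", "name", "cas", "formula", "class", "rt_min")]
  cmp$match_score <- NA_real_
  relative_content_table(percent, cmp, c(DY_1 = "DY", DM_1 = "DM"),
                         tol = 5e-3)
}

#' @rdname docynia_peak_table
#' @return `docynia_thresholds()`: a [threshold_table()] of odor thresholds
#'   (mg/kg, from standard odor-threshold compilations) and aroma
#'   descriptors for the 14 aroma-active compounds of the panel.
#' @export
docynia_thresholds <- function() {
  threshold_table(
    name = c(
      "1-Octanol", "Hexanal", "(E)-2-Hexenal", "Octanal",
      "Benzeneacetaldehyde", "(E)-2-Octenal", "2,6-Dimethyl-4-heptanone",
      "Butyl acetate", "Ethyl heptanoate", "Ethyl caprylate",
      "Phenethyl acetate", "Dihydro-\u03b2-ionone", "Geranylacetone",
      "\u03b2-Ionone"
    ),
    threshold_mg_per_kg = c(
      0.022, 0.005, 0.0031, 0.17, 0.0017, 0.0027, 9.3,
      0.01, 0.24, 0.04, 0.0067, 0.0017, 0.06, 0.00012
    ),
    descriptors = c(
      "green;citrus;floral;sweet",
      "green;grass;fruity",
      "green",
      "orange;green;herbal",
      "sweet;honey;floral",
      "green;herbal;banana",
      "green;fruity;pineapple;banana",
      "fruity;banana",
      "fruity;sweet;banana",
      "pineapple;fruity",
      "floral;rosy;sweet;honey",
      "cedar;woody;mahogany",
      "rose;floral;green;fruity",
      "woody;floral;sweet;fruity"
    )
  )
}

#' @rdname docynia_peak_table
#' @return `docynia_key_stats()`: tibble `id, name, vip, p` with the
#'   externally fitted OPLS-DA VIP scores and t-test p-values of the 23
#'   key compounds of this panel (the per-replicate areas behind them are
#'   not part of the dataset, so these serve as precomputed inputs to
#'   [screen_key_compounds()]).
#' @export
docynia_key_stats <- function() {
  tibble::tribble(
    ~id,   ~name,                               ~vip,  ~p,
    "C17", "Octanal",                           1.102, 0.000,
    "C37", "Geranylacetone",                    1.101, 0.000,
    "C26", "Butyl acetate",                     1.100, 0.002,
    "C36", "Dihydro-\u03b2-ionone",             1.099, 0.000,
    "C23", "2,6-Dimethyl-4-heptanone",          1.097, 0.000,
    "C14", "(E)-2-Hexenal",                     1.097, 0.000,
    "C10", "(6Z)-2,6-Dimethylocta-2,6-diene",   1.096, 0.000,
    "C13", "Hexanal",                           1.094, 0.000,
    "C38", "\u03b2-Ionone",                     1.094, 0.000,
    "C35", "Theaspirane",                       1.090, 0.001,
    "C24", "4,6-Dimethylheptan-2-one",          1.082, 0.001,
    "C18", "Benzeneacetaldehyde",               1.081, 0.002,
    "C25", "4,7,9-Megastigmatrien-3-one",       1.070, 0.002,
    "C19", "(E)-2-Octenal",                     1.068, 0.003,
    "C40", "Farnesene",                         1.060, 0.008,
    "C11", "1-Octanol",                         1.059, 0.005,
    "C32", "Phenethyl acetate",                 1.059, 0.005,
    "C5",  "4-Methyldodecane",                  1.022, 0.027,
    "C28", "Ethyl heptanoate",                  1.019, 0.012,
    "C42", "2-Ethylfuran",                      1.014, 0.001,
    "C31", "Ethyl caprylate",                   1.009, 0.017,
    "C4",  "Dodecane",                          1.009, 0.034,
    "C8",  "7,9-Dimethylhexadecane",            1.001, 0.024
  )
}

# id, class, rt (min), name, cas, formula, DY / DM group-mean relative
# content (%); NA = not detected in that group
docynia_compound_data <- function() {
  tibble::tribble(
    ~id,   ~class,     ~rt_min, ~name,                             ~cas,         ~formula,      ~dy,    ~dm,
    "C1",  "alkane",   11.69, "4-Methyldecane",                    "2847-72-5",  "C11H24",      0.03,   0.02,
    "C2",  "alkane",   12.70, "5-Ethyl-2-methyloctane",            "62016-18-6", "C11H24",      0.09,   0.06,
    "C3",  "alkane",   12.88, "5-Methylundecane",                  "1632-70-8",  "C12H26",      0.07,   0.03,
    "C4",  "alkane",   17.06, "Dodecane",                          "112-40-3",   "C12H26",      0.07,   0.04,
    "C5",  "alkane",   17.65, "4-Methyldodecane",                  "6117-97-1",  "C13H28",      0.04,   0.02,
    "C6",  "alkane",   21.55, "2-Methyltridecane",                 "1560-96-9",  "C14H30",      0.02,   0.01,
    "C7",  "alkane",   22.51, "Tetradecane",                       "629-59-4",   "C14H30",      0.12,   0.07,
    "C8",  "alkane",   25.84, "7,9-Dimethylhexadecane",            "21164-95-4", "C18H38",      0.37,   0.20,
    "C9",  "alkane",   31.20, "Phytane",                           "638-36-8",   "C20H42",      0.03,   0.02,
    "C10", "alkene",   12.56, "(6Z)-2,6-Dimethylocta-2,6-diene",   "2492-22-0",  "C10H18",      0.04,   0.15,
    "C11", "alcohol",  13.18, "1-Octanol",                         "111-87-5",   "C8H18O",      1.88,   0.93,
    "C12", "aldehyde",  5.37, "3-Hexenal",                         "4440-65-7",  "C6H10O",      0.23,   0.12,
    "C13", "aldehyde",  5.42, "Hexanal",                           "66-25-1",    "C6H12O",      0.11,   0.31,
    "C14", "aldehyde",  6.72, "(E)-2-Hexenal",                     "6728-26-3",  "C6H10O",      0.39,   1.49,
    "C15", "aldehyde",  8.36, "(E,E)-2,4-Hexadienal",              "142-83-6",   "C6H8O",       0.16,   0.11,
    "C16", "aldehyde",  9.66, "(E)-2-Heptenal",                    "18829-55-5", "C7H12O",      0.07,   0.11,
    "C17", "aldehyde", 11.08, "Octanal",                           "124-13-0",   "C8H16O",      0.01,   0.04,
    "C18", "aldehyde", 12.31, "Benzeneacetaldehyde",               "122-78-1",   "C8H8O",       0.03,   0.15,
    "C19", "aldehyde", 12.75, "(E)-2-Octenal",                     "2548-87-0",  "C8H14O",      0.06,   0.07,
    "C20", "ketone",    3.24, "2,3-Butanedione",                   "431-03-8",   "C4H6O2",      3.76,   2.34,
    "C21", "ketone",    7.69, "2-Heptanone",                       "110-43-0",   "C7H14O",      2.08,   1.28,
    "C22", "ketone",    9.73, "5-Methylhex-4-en-3-one",            "13905-10-7", "C7H12O",      0.21,   0.11,
    "C23", "ketone",   10.09, "2,6-Dimethyl-4-heptanone",          "108-83-8",   "C9H18O",      4.97,   2.61,
    "C24", "ketone",   10.61, "4,6-Dimethylheptan-2-one",          "19549-80-5", "C9H18O",      0.15,   0.08,
    "C25", "ketone",   27.91, "4,7,9-Megastigmatrien-3-one",       "38818-55-2", "C13H18O",     0.02,   0.02,
    "C26", "ester",     5.73, "Butyl acetate",                     "123-86-4",   "C6H12O2",     0.001,  0.03,
    "C27", "ester",    10.85, "Butyl butanoate",                   "109-21-7",   "C8H16O2",     NA,     0.11,
    "C28", "ester",    13.97, "Ethyl heptanoate",                  "106-30-9",   "C9H18O2",    10.12,   4.87,
    "C29", "ester",    14.72, "Methyl octylate",                   "111-11-5",   "C9H18O2",     0.12,   0.06,
    "C30", "ester",    16.72, "Butyl hexanoate",                   "626-82-4",   "C10H20O2",    NA,     0.90,
    "C31", "ester",    16.91, "Ethyl caprylate",                   "106-32-1",   "C10H20O2",   20.29,   9.13,
    "C32", "ester",    18.57, "Phenethyl acetate",                 "103-45-7",   "C10H12O2",   40.69,  24.51,
    "C33", "ester",    22.08, "Hexyl hexanoate",                   "6378-65-0",  "C12H24O2",    NA,     0.72,
    "C34", "ester",    28.31, "Benzylcarbinyl caproate",           "6290-37-5",  "C14H20O2",    NA,     0.46,
    "C35", "terpene",  20.33, "Theaspirane",                       "36431-72-8", "C13H22O",    12.19,  34.90,
    "C36", "terpene",  23.34, "Dihydro-\u03b2-ionone",             "17283-81-7", "C13H22O",     0.13,   0.70,
    "C37", "terpene",  23.67, "Geranylacetone",                    "3796-70-1",  "C13H22O",     0.34,   0.60,
    "C38", "terpene",  24.49, "\u03b2-Ionone",                     "14901-07-6", "C13H20O",     0.99,   0.27,
    "C39", "terpene",  24.76, "cis-\u03b1-Bergamotene",            "18252-46-5", "C15H24",      NA,     0.69,
    "C40", "terpene",  25.16, "Farnesene",                         "502-61-4",   "C15H24",      0.02,  11.38,
    "C41", "terpene",  27.27, "cis-Bisabolene",                    "53585-13-0", "C15H24",      NA,     0.26,
    "C42", "furan",     3.59, "2-Ethylfuran",                      "3208-16-0",  "C6H8O",       0.09,   0.04
  )
}
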