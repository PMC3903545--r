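# Shared fixtures, built in code.

nbib_two_records <- function() {
  c(
    "PMID- 100001",
    "TI  - Influenza vaccination in the elderly: a case-control",
    "      study",
    "AB  - We assessed vaccine effectiveness among elderly",
    "      community-dwelling adults.",
    "JT  - Journal of Epidemiology",
    "MH  - Influenza Vaccines",
    "MH  - *Aged",
    "",
    "PMID- 100002",
    "TI  - Rapid diagnostic tests for malaria",
    "AB  - Accuracy of rapid tests in endemic regions.",
    "JT  - Tropical Medicine",
    "MH  - Malaria/diagnosis",
    "OT  - rapid test"
  )
}

ris_one_record <- function() {
  c(
    "TY  - JOUR",
    "TI  - Galactomannan detection for invasive aspergillosis",
    "AB  - Diagnostic accuracy of serum galactomannan.",
    "JO  - Mycology Journal",
    "KW  - Aspergillosis",
    "KW  - Diagnosis",
    "KW  - Serum",
    "AN  - 200001",
    "ER  - "
  )
}

tiny_labeled_corpus <- function() {
  corpus(
    id = c("a", "b", "c", "d"),
    title = c("Influenza vaccine trial", "Malaria test accuracy",
              "Vaccine immunology study", "Transplant outcomes"),
    abstract = c("A randomized trial of influenza vaccines.",
                 "Rapid malaria tests in the field.",
                 "Immune responses to vaccination.",
                 "Outcomes after organ transplant."),
    journal = c("J One", "J Two", "J One", "J Three"),
    indexing = list(c("Influenza Vaccines", "*Aged"),
                    c("Malaria/diagnosis"),
                    c("Vaccination"),
                    character(0)),
    label = c("include", "exclude", "include", "exclude"),
    review_id = "tiny"
  )
}

tiny_lexicon <- function() {
  tibble::tibble(
    term = c("elderly population", "vaccination", "influenza vaccination",
             "malaria"),
    concept = c("Elderly_population_group", "Vaccination",
                "Influenza_vaccination", "Malaria")
  )
}

# a small, strongly separable labeled corpus for protocol tests
separable_corpus <- function(n = 160, eligible = 0.25, effect = 40,
                             seed = 11) {
  generate_screening_corpus(generator_config(
    n_docs = n, eligible_rate = eligible, vocab_size = 400,
    n_discriminative_terms = 12, effect = effect,
    missing_abstract_rate = 0, seed = seed
  ))
}

# printed five-review mean-performance matrices (reviews x feature sets);
# columns: alphanumeric+, alphabetic, topics, SR concepts, indexing
table4_matrix <- function(metric = c("f3", "recall", "precision",
                                     "classification_error")) {
  metric <- match.arg(metric)
  sets <- c("alphanumeric", "alphabetic", "topics", "concepts", "indexing")
  reviews <- c("ameloblastoma", "influenza", "galactomannan", "malaria",
               "organ_transplant")
  vals <- switch(metric,
    f3 = c(75.11, 74.52, 71.51, 68.22, 68.68,
           65.52, 57.16, 61.97, 59.38, 63.11,
           87.31, 90.73, 74.73, 78.88, 74.13,
           88.09, 89.30, 86.42, 83.33, 81.85,
           57.82, 64.39, 59.17, 54.24, 52.52),
    recall = c(80.01, 79.98, 78.27, 87.78, 81.76,
               76.44, 59.68, 73.63, 76.33, 77.70,
               89.37, 96.81, 96.81, 95.74, 92.55,
               90.98, 95.77, 93.80, 92.67, 90.69,
               59.77, 71.87, 74.95, 74.14, 80.31),
    precision = c(49.15, 46.47, 40.39, 26.89, 28.21,
                  30.08, 42.00, 25.83, 19.82, 23.50,
                  72.38, 58.12, 24.51, 30.51, 26.64,
                  68.75, 55.55, 50.60, 43.73, 43.78,
                  46.05, 33.25, 20.45, 17.05, 13.82),
    classification_error = c(6.66, 7.15, 8.73, 20.31, 14.39,
                             12.31, 7.16, 13.82, 19.24, 15.90,
                             1.91, 3.14, 12.92, 9.51, 11.33,
                             6.33, 10.09, 12.20, 15.78, 15.74,
                             5.06, 7.78, 14.29, 18.90, 26.08)
  )
  matrix(vals, nrow = 5, byrow = TRUE,
         dimnames = list(reviews, sets))
}
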