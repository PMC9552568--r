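Package: scdlink
Title: Multi-Source Surveillance Linkage and Case Classification for
    Sickle Cell Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-based sickle cell disease (SCD)
    surveillance built on linked administrative and clinical data. The
    package classifies ICD-9-CM/ICD-10-CM diagnosis codes into SCD,
    sickle-cell-trait and other categories; generates seeded synthetic
    populations with the five surveillance source files (newborn
    screening, clinic case reports, Medicaid/CHIP claims, hospital and
    emergency department discharges, death certificates) including
    identifier noise and diagnostic miscoding; links and deduplicates
    records with a deterministic exact-match cascade plus Fellegi-Sunter
    probabilistic scoring; assembles a hub-and-spoke master person index;
    applies the confirmed/probable/possible surveillance case definition;
    and produces cumulative and annual prevalence reports with
    person-years, migration-adjusted annual counts, genotype/sex/age
    strata, and truth-based evaluation on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    igraph,
    jsonlite,
    readr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
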