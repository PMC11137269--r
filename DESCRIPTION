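Package: mmpatterns
Title: Multimorbidity Pattern Discovery and Trajectory Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify multimorbidity patterns in electronic
    health record cohorts and follow their evolution over time. Builds
    per-wave binary disease matrices from long-format chronic-disease
    records, partitions patients with k-means clustering under the
    Jaccard distance, selects the number of patterns with the
    Calinski-Harabasz index subject to a pattern-validity rule based on
    prevalence ratios, links wave-specific patterns into per-patient
    trajectories with absorbing death and loss states, and estimates
    age- and sex-adjusted odds ratios for mortality and acute-disease
    associations. Includes a synthetic-cohort generator with planted
    cluster structure so the full pipeline can be exercised and
    validated without access to restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, tools, nnet, jsonlite, yaml
Suggests: testthat (>= 3.0.0), e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
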