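# Shared fixtures: shipped catalog, cost table and audit counts.
the_catalog <- rms_catalog()
the_costs <- read_unit_costs()
the_audit <- rms_audit()
the_printed <- pathway_costs(the_catalog, the_costs, source = "printed")
the_groups <- pathway_groups()

# narrative affected counts with the pathway 2/3 split left open
narrative_affected <- stats::setNames(c(9, NA, NA, 7, 0, 23, 3, 4, 12, 16),
                                      1:10)
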