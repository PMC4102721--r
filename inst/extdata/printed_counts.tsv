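# counts printed in the published study text, used as expected values for
# the arithmetic cross-checks in fixture_checks()
name	value
total_scores	12187
ambiguous_clones	2
putative_clones	8100
promiscuity_limit	3000
clones_ge4_excl	467
selected_clones	738
crit_b_selected	232
end_marker_selected	39
unambiguous_clones	7228
both_nt_clones	7230
conflicting_clones	60
multi_marker_clones	1586
false_positive_scores	25
confirmed_clone_scores	1055
unverified_scores	37
untestable_scores	12
crit_b_confirmed	16
end_marker_confirmed	11
contig_members_ge4	170
contig_members	236
amplicon_sites_conserved	46
amplicon_sites_tested	61
express_two_nt_assays	39
assays_total	52
confirmed_clones	197
confirmed_clones_a	114
confirmed_clones_c	83
false_negative_scores	114
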