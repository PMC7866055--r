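# Ligand-binding analysis defaults.
contact_cutoff_nm: 0.35
# Conserved nucleotide-binding arginines contacted by the ATP phosphate
# groups (author numbering).
atp_arginines: [88, 185, 279]
# Fatty-acid-anion binding-site residue monitored for salt-bridge
# formation (wild type arginine; the serine mutant forms none).
fa_site_resid: 60
# Replica protocol: independently seeded replicas analyzed over the last
# half of each run (20 ns replicas -> final 10 ns).
replica_window: [0.5, 1.0]
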