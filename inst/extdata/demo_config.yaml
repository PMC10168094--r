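# Demo configuration for the synthetic end-to-end pipeline.
# 4 x 6 cells of 2.81 degrees starting at 50 N, 30 index years (1977-2006),
# two sites of eight trees per cell.
seed: 1
grid_n_lat: 4
grid_n_lon: 6
n_years: 30
first_year: 1977
sites_per_cell: 2
trees_per_site: 8
eps_threshold: 0.85
alpha: 0.05
window_span: 25
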