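# Demonstration scenario: prevailing northeasterly winds.
# A southwestward alongshore jet sheds cyclonic cross-shelf filaments.
# Site geometries are illustrative placeholders for the four coastal source
# areas and two offshore platform fields -- NOT surveyed coordinates.
name: northeast-demo
grid:
  lon_range: [-44.5, -41.3]
  lat_range: [-24.2, -22.95]
  spacing_deg: 0.02
  z_levels: [-50.0, 0.0]
  coast_lat: -23.0
scenario:
  name: northeast
  duration_days: 20
  cadence_hours: 6
  jet_speed: 0.25
  jet_width_km: 20
  jet_offshore_km: 25
  filaments:
    - origin: [-42.0, -23.0]
      length_km: 60
      width_km: 5
      peak_speed: 0.35
      polarity: cyclonic
    - origin: [-43.5, -23.0]
      length_km: 45
      width_km: 5
      peak_speed: 0.25
      polarity: cyclonic
sites:
  - {name: AC, kind: circle, lon: -42.05, lat: -23.09, radius_km: 4, role: source}
  - {name: CI, kind: circle, lon: -43.17, lat: -23.09, radius_km: 4, role: source}
  - {name: IGB, kind: circle, lon: -44.15, lat: -23.09, radius_km: 4, role: source}
  - {name: AH, kind: circle, lon: -41.55, lat: -23.09, radius_km: 4, role: source}
  - name: P1
    kind: polygon
    role: destination
    vertices: [[-42.3, -23.75], [-41.6, -23.75], [-41.6, -23.35], [-42.3, -23.35]]
  - name: P2
    kind: polygon
    role: destination
    vertices: [[-43.3, -24.0], [-42.5, -24.0], [-42.5, -23.55], [-43.3, -23.55]]
schedule:
  particles_per_day: 100
  n_days: 5
  release_depth: 0.0
physics:
  kappa_v: 1.0e-5
  dt_seconds: 120
seeds:
  release: 101
  walk: 202
output:
  dir: null
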