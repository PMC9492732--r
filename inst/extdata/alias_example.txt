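# Example column-alias mapping for read_trait_csv():
# one "source_column: schema_column" pair per line.
SpeciesName: species
SiteID: site_id
Lat: latitude
GrowthForm: growth_form
LeafArea_cm2: leaf_area_cm2
LeafDryMass_g: dry_mass_g
LeafFreshMass_g: fresh_mass_g
LDMC: ldmc
Aarea: photo_area_umol_m2_s
Nmass_g: leaf_n_mass_g
Pmass_g: leaf_p_mass_g
Tmeas: temp_measurement_c
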