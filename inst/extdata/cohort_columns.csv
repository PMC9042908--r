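column,type,units,description
eye_id,string,,unique eye identifier
group,string,,"optional; improved / maintained_worse; derived from BCVA change when absent"
age,numeric,years,age at baseline
age_ge_55,integer 0/1,,age at or above 55 years
sex,string,,M or F
axial_length,numeric,mm,ocular axial length
spherical_equivalent,numeric,diopters,spherical equivalent refraction
bcva_baseline,numeric,ETDRS letters,best-corrected visual acuity at baseline (0-100)
bcva_12m,numeric,ETDRS letters,best-corrected visual acuity at 12 months (0-100)
sfct,numeric,micrometres,subfoveal choroidal thickness
cft,numeric,micrometres,central foveal thickness
ez_grade,integer 0/1,,ellipsoid zone integrity: 0 intact or mild disruption; 1 severe
elm_grade,integer 0/1,,external limiting membrane integrity: 0 intact or mild; 1 severe
srf_present,integer 0/1,,subretinal fluid present
morphology,string,,medusa_seafan or tangled lesion pattern
branching,integer 0/1,,tiny branching capillaries present
loops,integer 0/1,,anastomotic arcades or loops present
dark_halo,integer 0/1,,perilesional hypointense halo present
cnv_size,numeric,mm2,lesion footprint area
vessel_density,numeric,percent,binarized vessel area over lesion area
vessel_length_density,numeric,percent,skeleton area over lesion area
vessel_diameter,numeric,ratio,vessel density / vessel length density
vessel_tortuosity,numeric,ratio,mean branch arc/chord ratio (>= 1)
fractal_dimension,numeric,,box-counting dimension of the lesion network
lacunarity,numeric,,gliding-box lacunarity summary
n_injections,integer,count,anti-VEGF injections within 12 months
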