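study_id,country,treatment,role,n,outcome_id,followup_weeks,kind,events,mean_change,sd,scale_name,direction,risk_of_bias
nct2012,UK,cannabinoids,I,56,pain4w,7,continuous,,,,NRS,higher-is-worse,high
nct2012,UK,placebo,C,60,pain4w,7,continuous,,,,NRS,higher-is-worse,high
cardenas2013,USA,pregabalin,I,111,pain4w,16,continuous,,,,NRS,higher-is-worse,high
cardenas2013,USA,placebo,C,108,pain4w,16,continuous,,,,NRS,higher-is-worse,high
agarwal2017,India,amitriptyline,I,74,pain4w,3,continuous,,,,SFMPQ2,higher-is-worse,high
agarwal2017,India,lamotrigine,C,73,pain4w,3,continuous,,,,SFMPQ2,higher-is-worse,high
amr2010,Egypt,ketamine,I,20,pain4w,4,continuous,,,,VAS-100,higher-is-worse,moderate
amr2010,Egypt,gabapentin,C,20,pain4w,4,continuous,,,,VAS-100,higher-is-worse,moderate
amr2011,Egypt,ketamine,I,20,pain4w,8,continuous,,,,VAS-100,higher-is-worse,moderate
amr2011,Egypt,gabapentin,C,20,pain4w,8,continuous,,,,VAS-100,higher-is-worse,moderate
andresen2016,Denmark,cannabinoids,I,36,pain4w,12,continuous,,,,NRS,higher-is-worse,moderate
andresen2016,Denmark,placebo,C,37,pain4w,12,continuous,,,,NRS,higher-is-worse,moderate
salinas2012,Colombia,carbamazepine,I,24,pain4w,24,continuous,,,,VAS-100,higher-is-worse,high
salinas2012,Colombia,placebo,C,22,pain4w,24,continuous,,,,VAS-100,higher-is-worse,high
siddall2006,Australia,pregabalin,I,70,pain4w,12,continuous,,,,NRS,higher-is-worse,high
siddall2006,Australia,placebo,C,67,pain4w,12,continuous,,,,NRS,higher-is-worse,high
tai2016,USA,gabapentin,I,7,pain4w,10,continuous,,,,NPS,higher-is-worse,moderate
tai2016,USA,placebo,C,7,pain4w,10,continuous,,,,NPS,higher-is-worse,moderate
vranken2008,Netherlands,pregabalin,I,20,pain4w,4,continuous,,,,VAS-10,higher-is-worse,moderate
vranken2008,Netherlands,placebo,C,20,pain4w,4,continuous,,,,VAS-10,higher-is-worse,moderate
vranken2011,Netherlands,duloxetine,I,18,pain4w,8,continuous,,,,VAS-10,higher-is-worse,high
vranken2011,Netherlands,placebo,C,18,pain4w,8,continuous,,,,VAS-10,higher-is-worse,high
yilmaz2015,Turkey,pregabalin,I,15,pain4w,18,continuous,,,,VAS-10,higher-is-worse,moderate
yilmaz2015,Turkey,gabapentin,C,15,pain4w,18,continuous,,,,VAS-10,higher-is-worse,moderate
chun2019,USA,btxa,I,5,pain4w,12,continuous,,,,NPRS,higher-is-worse,moderate
chun2019,USA,placebo,C,3,pain4w,12,continuous,,,,NPRS,higher-is-worse,moderate
finnerup2009,Denmark,levetiracetam,I,18,pain4w,5,continuous,,,,NRS,higher-is-worse,high
finnerup2009,Denmark,placebo,C,18,pain4w,5,continuous,,,,NRS,higher-is-worse,high
han2016,Korea,btxa,I,20,pain4w,8,continuous,,,,VAS-100,higher-is-worse,high
han2016,Korea,placebo,C,20,pain4w,8,continuous,,,,VAS-100,higher-is-worse,high
kaydok2014,Turkey,gabapentin,I,14,pain4w,4,continuous,,,,VAS-100,higher-is-worse,moderate
kaydok2014,Turkey,pregabalin,C,14,pain4w,4,continuous,,,,VAS-100,higher-is-worse,moderate
levendoglu2004,Turkey,gabapentin,I,10,pain4w,8,continuous,,,,VAS-100,higher-is-worse,moderate
levendoglu2004,Turkey,placebo,C,10,pain4w,8,continuous,,,,VAS-100,higher-is-worse,moderate
norrbrink2009,Sweden,tramadol,I,23,pain4w,4,continuous,,,,MPI,higher-is-worse,high
norrbrink2009,Sweden,placebo,C,12,pain4w,4,continuous,,,,MPI,higher-is-worse,high
rintala2007,USA,amitriptyline,I,28,pain4w,8,continuous,,,,VAS-100,higher-is-worse,moderate
rintala2007,USA,gabapentin,I,26,pain4w,8,continuous,,,,VAS-100,higher-is-worse,moderate
rintala2007,USA,placebo,C,25,pain4w,8,continuous,,,,VAS-100,higher-is-worse,moderate
rintala2010,USA,cannabinoids,I,7,pain4w,4,continuous,,,,NRS,higher-is-worse,moderate
rintala2010,USA,placebo,C,7,pain4w,4,continuous,,,,NRS,higher-is-worse,moderate
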