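crop_group,wiews_total,genesys_total,distinct,treaty,sgsv,complete
Cereals,3095022,1061698,1223255,2065416,495410,TRUE
Food Legumes,1187206,397945,437496,734065,166339,TRUE
Forage Crops,389225,161796,139298,47995,35103,FALSE
Roots and Tubers,183044,66708,68549,71105,17669,TRUE
Vegetables,397069,137084,107672,73209,17988,FALSE
Oil Crops,140196,21030,39729,20511,4068,FALSE
Major crops total,5979663,2040606,2185452,3117472,766292,NA
All crops total,7205007,2334747,2498098,3319398,774601,NA
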