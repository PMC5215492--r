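label,class
tree,natural
yard,natural
cloud,natural
garden,natural
backyard,natural
plant,natural
flower,natural
grass,natural
waterway,natural
habitat,natural
shrub,natural
sea,natural
natural environment,natural
lawn,natural
plain,natural
coast,natural
forest,natural
green,natural
woodland,natural
shore,natural
residential area,artificial
property,artificial
vehicle,artificial
estate,artificial
suburb,artificial
town,artificial
house,artificial
road,artificial
condominium,artificial
automobile,artificial
asphalt,artificial
facade,artificial
walkway,artificial
home,artificial
flooring,artificial
cottage,artificial
hacienda,artificial
transport,artificial
driveway,artificial
real estate,artificial
area,ambiguous
neighbourhood,ambiguous
horizon,ambiguous
lane,ambiguous
produce,ambiguous
path,ambiguous
outdoor structure,ambiguous
panorama,ambiguous
farm,ambiguous
blue,ambiguous
skyline,ambiguous
phenomenon,ambiguous
reflection,ambiguous
red,ambiguous
arch,ambiguous
stone wall,ambiguous
yellow,ambiguous
resort,ambiguous
vacation,ambiguous
circle,ambiguous
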